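// Low-level numerical kernels for the encoder-decoder segmentation network:
// same-padded 2-D convolution (im2col + GEMM), 2x2 max-pooling that records
// argmax indices, index-driven max-unpooling, and 8-connectivity component
// labeling. Feature maps are rows x cols x channels cubes (R column-major).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the (kh*kw*cin) x (H*W) patch matrix with symmetric zero padding
// of (k-1)/2 so spatial size is preserved. Row ordering matches the R
// weight array layout (kh, kw, cin, cout) flattened column-major.
static arma::mat im2col(const arma::cube& x, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pr = (kh - 1) / 2, pc = (kw - 1) / 2;
  arma::mat K(kh * kw * C, (arma::uword)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& plane = x.slice(c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        // source pixel (r + i - pr, s + j - pc) for output pixel (r, s)
        for (int s = 0; s < W; ++s) {
          const int sc = s + j - pc;
          if (sc < 0 || sc >= W) continue;
          const int r0 = std::max(0, pr - i), r1 = std::min(H, H + pr - i);
          for (int r = r0; r < r1; ++r)
            K(row, r + (arma::uword)H * s) = plane(r + i - pr, sc);
        }
      }
    }
  }
  return K;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::vec& w_flat,
                      const arma::vec& bias, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = bias.n_elem;
  arma::mat Wm(const_cast<double*>(w_flat.memptr()), kh * kw * Cin, Cout,
               false, true);
  arma::mat out;
  if (kh == 1 && kw == 1) {
    arma::mat X(const_cast<double*>(x.memptr()), (arma::uword)H * W, Cin,
                false, true);
    out = X * Wm;                       // 1x1 conv needs no patch matrix
  } else {
    out = im2col(x, kh, kw).t() * Wm;
  }
  out.each_row() += bias.t();
  return arma::cube(out.memptr(), H, W, Cout);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::vec& w_flat,
                const arma::cube& gout, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  arma::mat Wm(const_cast<double*>(w_flat.memptr()), kh * kw * Cin, Cout,
               false, true);
  arma::mat G(const_cast<double*>(gout.memptr()), (arma::uword)H * W, Cout,
              false, true);
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gw, gK;
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  if (kh == 1 && kw == 1) {
    arma::mat X(const_cast<double*>(x.memptr()), (arma::uword)H * W, Cin,
                false, true);
    gw = X.t() * G;
    arma::mat gX = G * Wm.t();
    gx = arma::cube(gX.memptr(), H, W, Cin);
  } else {
    arma::mat K = im2col(x, kh, kw);
    gw = K * G;                         // (kh*kw*Cin) x Cout
    gK = Wm * G.t();                    // (kh*kw*Cin) x (H*W)
    const int pr = (kh - 1) / 2, pc = (kw - 1) / 2;
    for (int c = 0; c < Cin; ++c) {
      arma::mat& plane = gx.slice(c);
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int row = i + kh * (j + kw * c);
          for (int s = 0; s < W; ++s) {
            const int sc = s + j - pc;
            if (sc < 0 || sc >= W) continue;
            const int r0 = std::max(0, pr - i), r1 = std::min(H, H + pr - i);
            for (int r = r0; r < r1; ++r)
              plane(r + i - pr, sc) += gK(row, r + (arma::uword)H * s);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = arma::vec(gw.memptr(),
                      gw.n_elem), _["gb"] = gb);
}

// 2x2 / stride-2 max pooling, floor on odd dims. idx holds the 1-based
// linear index (within the full input cube) of each window maximum; ties
// go to the first element in row-major window scan order.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("spatial dims < 2 at pooling");
  arma::cube out(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const arma::uword off = (arma::uword)c * H * W;
    for (int s = 0; s < Wo; ++s) {
      for (int r = 0; r < Ho; ++r) {
        double best = -std::numeric_limits<double>::infinity();
        arma::uword bi = 0;
        // row-major scan: (0,0), (0,1), (1,0), (1,1); strict > keeps first
        for (int di = 0; di < 2; ++di)
          for (int dj = 0; dj < 2; ++dj) {
            const double v = x(2 * r + di, 2 * s + dj, c);
            if (v > best) { best = v; bi = (2 * r + di) +
              (arma::uword)H * (2 * s + dj) + off; }
          }
        out(r, s, c) = best;
        idx[r + Ho * (s + (arma::uword)Wo * c)] = (int)(bi + 1);
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["in_rows"] = H, _["in_cols"] = W);
}

// Scatter: place each pooled value back at its recorded argmax position.
// [[Rcpp::export(name = ".unpool_fwd")]]
arma::cube unpool_fwd(const arma::cube& x, const IntegerVector& idx,
                      const int out_rows, const int out_cols) {
  const int C = x.n_slices;
  if ((int)idx.size() != (int)x.n_elem)
    stop("pooling trace does not match input size");
  arma::cube out(out_rows, out_cols, C, arma::fill::zeros);
  const double* xp = x.memptr();
  double* op = out.memptr();
  for (int k = 0; k < (int)x.n_elem; ++k) op[idx[k] - 1] = xp[k];
  return out;
}

// Gather: gradient of unpool_fwd (and of maxpool when applied to gout).
// [[Rcpp::export(name = ".unpool_bwd")]]
arma::cube unpool_bwd(const arma::cube& gout, const IntegerVector& idx,
                      const int in_rows, const int in_cols, const int ch) {
  arma::cube gx(in_rows, in_cols, ch);
  const double* gp = gout.memptr();
  double* xp = gx.memptr();
  for (int k = 0; k < (int)gx.n_elem; ++k) xp[k] = gp[idx[k] - 1];
  return gx;
}

// 8-connectivity connected-component labeling of a binary matrix.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < W; ++s) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, s) == 0 || lab(r, s) != 0) continue;
      ++next;
      stack.push_back(r + H * s);
      lab(r, s) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            const int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + H * nc);
            }
          }
      }
    }
  }
  return lab;
}
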