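# Forward and backward passes. Feature maps are rows x cols x channels
# arrays; minibatches are lists of such arrays. Batch norm uses minibatch
# statistics (instance statistics at batch size 1) in both training and
# prediction; biased variance, eps 1e-5.

.bn_eps <- 1e-5

.relu <- function(x) { x[x < 0] <- 0; x }

# Batch-norm forward over a list of cubes sharing dims.
.bn_fwd <- function(xs, gamma, beta) {
  hw <- dim(xs[[1]])[1] * dim(xs[[1]])[2]
  n <- hw * length(xs)
  s1 <- Reduce(`+`, lapply(xs, function(x) .colSums(x, hw, dim(x)[3])))
  s2 <- Reduce(`+`, lapply(xs, function(x) .colSums(x * x, hw, dim(x)[3])))
  mu <- s1 / n
  v <- pmax(s2 / n - mu^2, 0)
  inv <- 1 / sqrt(v + .bn_eps)
  xhat <- lapply(xs, function(x) sweep(sweep(x, 3, mu), 3, inv, `*`))
  out <- lapply(xhat, function(xh) sweep(sweep(xh, 3, gamma, `*`), 3, beta, `+`))
  list(out = out, xhat = xhat, inv = inv, mu = mu, n = n)
}

.bn_bwd <- function(cache, gamma, gouts) {
  hw <- dim(gouts[[1]])[1] * dim(gouts[[1]])[2]
  ch <- dim(gouts[[1]])[3]
  dgamma <- Reduce(`+`, Map(function(g, xh) .colSums(g * xh, hw, ch),
                            gouts, cache$xhat))
  dbeta <- Reduce(`+`, lapply(gouts, function(g) .colSums(g, hw, ch)))
  n <- cache$n
  # dx = gamma*inv * (g - mean(g) - xhat * mean(g*xhat))
  gxs <- Map(function(g, xh) {
    t1 <- sweep(g, 3, dbeta / n)
    t2 <- sweep(xh, 3, dgamma / n, `*`)
    sweep(t1 - t2, 3, gamma * cache$inv, `*`)
  }, gouts, cache$xhat)
  list(gx = gxs, dgamma = dgamma, dbeta = dbeta)
}

.conv_fwd_batch <- function(xs, p, k)
  lapply(xs, function(x) .conv2d_fwd(x, p$w, p$b, k, k))

# Single-sample encoder dense block. Returns the exported first-conv
# feature (post BN+ReLU), the pooled bottleneck output, and the pooling
# trace entry used by the paired decoder unpooling layer.
#
#' Run one encoder dense block
#'
#' @param F_i Input feature map (rows x cols x channels array).
#' @param block_params List with elements `convA`, `bnA`, `convB`, `bneck`,
#'   `bnK` (as stored in an `rps_network` for block i).
#' @param kernel_size Convolution size (3).
#' @return List: `ea_feature` (first-conv output after batch-norm + ReLU,
#'   kept for the external dense path), `concat` (in-block dense feature),
#'   `bottleneck` (channel-limited feature), `pooled`, and `trace_entry`
#'   (argmax indices + pre-pool size).
#' @export
encoder_block_forward <- function(F_i, block_params, kernel_size = 3L) {
  if (dim(F_i)[3] != dim(block_params$convA$w)[3])
    stop("input channels do not match block input channels", call. = FALSE)
  if (any(dim(F_i)[1:2] < 2))
    stop("spatial dims < 2 at pooling", call. = FALSE)
  a <- .relu(.bn_fwd(list(.conv2d_fwd(F_i, block_params$convA$w,
                                      block_params$convA$b,
                                      kernel_size, kernel_size)),
                     block_params$bnA$gamma, block_params$bnA$beta)$out[[1]])
  b <- .conv2d_fwd(a, block_params$convB$w, block_params$convB$b,
                   kernel_size, kernel_size)
  P <- .abind3(a, b)
  z <- .relu(.bn_fwd(list(.conv2d_fwd(P, block_params$bneck$w,
                                      block_params$bneck$b, 1L, 1L)),
                     block_params$bnK$gamma, block_params$bnK$beta)$out[[1]])
  pl <- .maxpool2_fwd(z)
  list(ea_feature = a, concat = P, bottleneck = z, pooled = pl$out,
       trace_entry = list(idx = pl$idx, pre_rows = pl$in_rows,
                          pre_cols = pl$in_cols))
}

#' Run one decoder dense block
#'
#' Unpools its input with the paired encoder pooling trace, applies the two
#' decoder convolutions, concatenates their outputs with the encoder
#' feature imported over the external dense path, and channel-limits the
#' result through the bottleneck.
#'
#' @param G_j Input feature map.
#' @param ea_feature Encoder block's first-convolution feature (external
#'   dense path import).
#' @param trace_entry Pooling trace from the paired encoder block.
#' @param block_params List with elements `convB`, `bnB`, `convA`, `bneck`,
#'   `bnK`.
#' @param kernel_size Convolution size (3).
#' @return List: `unpooled`, `concat` (three-way dense feature), `out`
#'   (bottleneck output).
#' @export
decoder_block_forward <- function(G_j, ea_feature, trace_entry, block_params,
                                  kernel_size = 3L) {
  u <- .unpool_fwd(G_j, trace_entry$idx, trace_entry$pre_rows,
                   trace_entry$pre_cols)
  if (!all(dim(u)[1:2] == dim(ea_feature)[1:2]))
    stop("unpooled map and encoder feature have mismatched spatial dims",
         call. = FALSE)
  db <- .relu(.bn_fwd(list(.conv2d_fwd(u, block_params$convB$w,
                                       block_params$convB$b,
                                       kernel_size, kernel_size)),
                      block_params$bnB$gamma, block_params$bnB$beta)$out[[1]])
  da <- .conv2d_fwd(db, block_params$convA$w, block_params$convA$b,
                    kernel_size, kernel_size)
  Q <- .abind3(db, da, ea_feature)
  z <- .relu(.bn_fwd(list(.conv2d_fwd(Q, block_params$bneck$w,
                                      block_params$bneck$b, 1L, 1L)),
                     block_params$bnK$gamma, block_params$bnK$beta)$out[[1]])
  list(unpooled = u, concat = Q, out = z)
}

.abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[1:2]
  array(c(...), dim = c(d, sum(vapply(parts, function(p) dim(p)[3], 0L))))
}

.block_param_set <- function(net, side, i) {
  p <- net$params
  if (side == "enc")
    list(convA = p[[sprintf("EC%d-A", i)]], bnA = p[[sprintf("EC%d-A-bn", i)]],
         convB = p[[sprintf("EC%d-B", i)]], bneck = p[[sprintf("Bneck-%d", i)]],
         bnK = p[[sprintf("Bneck-%d-bn", i)]])
  else
    list(convB = p[[sprintf("DC%d-B", i)]], bnB = p[[sprintf("DC%d-B-bn", i)]],
         convA = p[[sprintf("DC%d-A", i)]],
         bneck = p[[sprintf("Bneck-%d", 9L - i)]],
         bnK = p[[sprintf("Bneck-%d-bn", 9L - i)]])
}

.softmax3 <- function(z) {
  m <- apply(z, c(1, 2), max)
  e <- exp(sweep(z, c(1, 2), m))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), `/`)
}

# Full forward over a minibatch (list of images). Caches every intermediate
# needed for backprop when keep_cache = TRUE.
.forward_batch <- function(net, xs, keep_cache = FALSE) {
  k <- net$spec$kernel_size
  p <- net$params
  cache <- list(enc = vector("list", 4), dec = vector("list", 4), xs = xs)
  cur <- xs
  for (i in 1:4) {
    nmA <- sprintf("EC%d-A", i); nmB <- sprintf("EC%d-B", i)
    nmK <- sprintf("Bneck-%d", i)
    a_pre <- .conv_fwd_batch(cur, p[[nmA]], k)
    bnA <- .bn_fwd(a_pre, p[[paste0(nmA, "-bn")]]$gamma,
                   p[[paste0(nmA, "-bn")]]$beta)
    a <- lapply(bnA$out, .relu)
    b <- .conv_fwd_batch(a, p[[nmB]], k)
    P <- Map(.abind3, a, b)
    z_pre <- .conv_fwd_batch(P, p[[nmK]], 1L)
    bnK <- .bn_fwd(z_pre, p[[paste0(nmK, "-bn")]]$gamma,
                   p[[paste0(nmK, "-bn")]]$beta)
    z <- lapply(bnK$out, .relu)
    if (any(dim(z[[1]])[1:2] < 2))
      stop("spatial dims < 2 at pooling; input image too small",
           call. = FALSE)
    pl <- lapply(z, .maxpool2_fwd)
    cache$enc[[i]] <- list(input = cur, bnA = bnA, a = a, P = P, bnK = bnK,
                           z = z, pool = pl)
    cur <- lapply(pl, `[[`, "out")
  }
  for (j in 4:1) {
    e <- cache$enc[[j]]
    nmB <- sprintf("DC%d-B", j); nmA <- sprintf("DC%d-A", j)
    nmK <- sprintf("Bneck-%d", 9L - j)
    u <- Map(function(g, pl) .unpool_fwd(g, pl$idx, pl$in_rows, pl$in_cols),
             cur, e$pool)
    db_pre <- .conv_fwd_batch(u, p[[nmB]], k)
    bnB <- .bn_fwd(db_pre, p[[paste0(nmB, "-bn")]]$gamma,
                   p[[paste0(nmB, "-bn")]]$beta)
    db <- lapply(bnB$out, .relu)
    da <- .conv_fwd_batch(db, p[[nmA]], k)
    Q <- Map(.abind3, db, da, e$a)
    z_pre <- .conv_fwd_batch(Q, p[[nmK]], 1L)
    bnK <- .bn_fwd(z_pre, p[[paste0(nmK, "-bn")]]$gamma,
                   p[[paste0(nmK, "-bn")]]$beta)
    z <- lapply(bnK$out, .relu)
    cache$dec[[j]] <- list(u = u, bnB = bnB, db = db, Q = Q, bnK = bnK, z = z)
    cur <- z
  }
  probs <- lapply(cur, .softmax3)
  if (!keep_cache) cache <- NULL
  list(probs = probs, logits = cur, cache = cache)
}

#' Forward pass: per-pixel class probabilities
#'
#' @param net An `rps_network`.
#' @param image rows x cols x channels numeric array; both spatial dims must
#'   be at least 16 (the encoder halves them four times).
#' @param want_trace Also return the four pooling trace entries?
#' @return rows x cols x n_classes probability array (per-pixel softmax), or
#'   a list `(prob, trace)` when `want_trace = TRUE`.
#' @examples
#' net <- build_network(rps_spec(block_widths = c(2, 3, 4, 5)), seed = 1)
#' pr <- network_forward(net, array(runif(24 * 16 * 3), c(24, 16, 3)))
#' range(apply(pr, c(1, 2), sum))  # each pixel sums to 1
#' @export
network_forward <- function(net, image, want_trace = FALSE) {
  stopifnot(inherits(net, "rps_network"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != net$spec$input_channels)
    stop("image must be rows x cols x ", net$spec$input_channels,
         " array", call. = FALSE)
  if (any(d[1:2] < 16))
    stop("input spatial dims must be at least 16 x 16 ",
         "(four spatial halvings)", call. = FALSE)
  fw <- .forward_batch(net, list(image), keep_cache = want_trace)
  if (!want_trace) return(fw$probs[[1]])
  trace <- lapply(fw$cache$enc, function(e)
    list(idx = e$pool[[1]]$idx, pre_rows = e$pool[[1]]$in_rows,
         pre_cols = e$pool[[1]]$in_cols))
  list(prob = fw$probs[[1]], trace = trace)
}

# Backward pass. glogits: list of gradients w.r.t. the final pre-softmax
# feature (the last bottleneck's post-ReLU output). Returns gradients named
# like net$params.
.backward_batch <- function(net, cache, glogits) {
  k <- net$spec$kernel_size
  p <- net$params
  grads <- list()
  gcur <- glogits
  acc_enc_a <- vector("list", 4)  # grads flowing back over the dense paths
  for (j in 1:4) {
    d <- cache$dec[[j]]
    e <- cache$enc[[j]]
    nmB <- sprintf("DC%d-B", j); nmA <- sprintf("DC%d-A", j)
    nmK <- sprintf("Bneck-%d", 9L - j)
    gz <- Map(function(g, z) { g[z <= 0] <- 0; g }, gcur, d$z)
    bnb <- .bn_bwd(d$bnK, p[[paste0(nmK, "-bn")]]$gamma, gz)
    grads[[paste0(nmK, "-bn")]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cb <- Map(function(x, g) .conv2d_bwd(x, p[[nmK]]$w, g, 1L, 1L),
              d$Q, bnb$gx)
    grads[[nmK]] <- .sum_conv_grads(cb, p[[nmK]]$w)
    gQ <- lapply(cb, `[[`, "gx")
    wB <- dim(d$db[[1]])[3]; wA <- dim(d$Q[[1]])[3] - wB - dim(e$a[[1]])[3]
    gdb1 <- lapply(gQ, function(g) g[, , seq_len(wB), drop = FALSE])
    gda <- lapply(gQ, function(g) g[, , wB + seq_len(wA), drop = FALSE])
    gea <- lapply(gQ, function(g)
      g[, , (wB + wA + 1):dim(g)[3], drop = FALSE])
    acc_enc_a[[j]] <- gea
    cb <- Map(function(x, g) .conv2d_bwd(x, p[[nmA]]$w, g, k, k), d$db, gda)
    grads[[nmA]] <- .sum_conv_grads(cb, p[[nmA]]$w)
    gdb <- Map(`+`, gdb1, lapply(cb, `[[`, "gx"))
    gdb <- Map(function(g, z) { g[z <= 0] <- 0; g }, gdb, d$db)
    bnb <- .bn_bwd(d$bnB, p[[paste0(nmB, "-bn")]]$gamma, gdb)
    grads[[paste0(nmB, "-bn")]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cb <- Map(function(x, g) .conv2d_bwd(x, p[[nmB]]$w, g, k, k), d$u, bnb$gx)
    grads[[nmB]] <- .sum_conv_grads(cb, p[[nmB]]$w)
    gu <- lapply(cb, `[[`, "gx")
    gcur <- Map(function(g, pl) .unpool_bwd(g, pl$idx, dim(pl$out)[1],
                                            dim(pl$out)[2], dim(pl$out)[3]),
                gu, e$pool)
  }
  for (i in 4:1) {
    e <- cache$enc[[i]]
    nmA <- sprintf("EC%d-A", i); nmB <- sprintf("EC%d-B", i)
    nmK <- sprintf("Bneck-%d", i)
    # gcur: grad at pooled output -> scatter back through the pooling
    gz <- Map(function(g, pl) .unpool_fwd(g, pl$idx, pl$in_rows, pl$in_cols),
              gcur, e$pool)
    gz <- Map(function(g, z) { g[z <= 0] <- 0; g }, gz, e$z)
    bnb <- .bn_bwd(e$bnK, p[[paste0(nmK, "-bn")]]$gamma, gz)
    grads[[paste0(nmK, "-bn")]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cb <- Map(function(x, g) .conv2d_bwd(x, p[[nmK]]$w, g, 1L, 1L),
              e$P, bnb$gx)
    grads[[nmK]] <- .sum_conv_grads(cb, p[[nmK]]$w)
    gP <- lapply(cb, `[[`, "gx")
    wi <- dim(e$a[[1]])[3]
    ga1 <- lapply(gP, function(g) g[, , seq_len(wi), drop = FALSE])
    gb <- lapply(gP, function(g) g[, , wi + seq_len(wi), drop = FALSE])
    cb <- Map(function(x, g) .conv2d_bwd(x, p[[nmB]]$w, g, k, k), e$a, gb)
    grads[[nmB]] <- .sum_conv_grads(cb, p[[nmB]]$w)
    ga <- Map(`+`, ga1, lapply(cb, `[[`, "gx"))
    ga <- Map(`+`, ga, acc_enc_a[[i]])      # external dense path gradient
    ga <- Map(function(g, pre) { g[pre <= 0] <- 0; g }, ga,
              lapply(e$bnA$out, identity))
    bnb <- .bn_bwd(e$bnA, p[[paste0(nmA, "-bn")]]$gamma, ga)
    grads[[paste0(nmA, "-bn")]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cb <- Map(function(x, g) .conv2d_bwd(x, p[[nmA]]$w, g, k, k),
              e$input, bnb$gx)
    grads[[nmA]] <- .sum_conv_grads(cb, p[[nmA]]$w)
    gcur <- lapply(cb, `[[`, "gx")
  }
  grads
}

.sum_conv_grads <- function(cb, w) {
  gw <- Reduce(`+`, lapply(cb, `[[`, "gw"))
  list(w = array(gw, dim = dim(w)),
       b = Reduce(`+`, lapply(cb, `[[`, "gb")))
}
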