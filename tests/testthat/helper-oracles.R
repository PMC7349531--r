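# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: parameter totals by direct per-layer arithmetic,
# connected components by queue-based flood fill, confusion counts and
# losses by explicit per-pixel loops.

# Per-layer arithmetic sum of trainable parameters for the 4-block
# encoder-decoder: conv = k*k*in*out + out (bias), batch-norm = 2*channels.
oracle_param_count <- function(widths, in_ch = 3L, n_classes = 2L, k = 3L) {
  total <- 0
  cin <- in_ch
  for (i in 1:4) {
    w <- widths[i]
    total <- total +
      (k * k * cin * w + w) + 2 * w +      # first conv (^^) + its BN
      (k * k * w * w + w) +                # second conv, plain
      (2 * w * w + w) + 2 * w              # 1x1 bottleneck on 2w + BN
    cin <- w
  }
  for (j in 4:1) {
    w <- widths[j]
    wa <- if (j > 1) widths[j - 1] else n_classes
    cat_ch <- 2 * w + wa
    total <- total +
      (k * k * w * w + w) + 2 * w +        # first decoder conv (^^) + BN
      (k * k * w * wa + wa) +              # second decoder conv, plain
      (cat_ch * wa + wa) + 2 * wa          # bottleneck on 3-way concat + BN
  }
  total
}

# 8-connectivity flood fill with an explicit queue.
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] == 0L || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] == 1L && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

oracle_confusion <- function(pred, truth) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (truth[i, j] == 1L) {
      if (pred[i, j] == 1L) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred[i, j] == 1L) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(TP = tp, FN = fn, FP = fp, TN = tn)
}

oracle_weighted_loss <- function(prob, mask, weights) {
  s <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    y <- mask[i, j] + 1L
    s <- s + weights[y] * (-log(max(prob[i, j, y], 1e-12)))
  }
  s / length(mask)
}

# Minimum-total-distance assignment by exhaustive permutation (<= 6 regions),
# respecting the matching radius.
oracle_assignment <- function(ca, cb, max_distance) {
  na <- nrow(ca); nb <- nrow(cb)
  D <- sqrt(outer(ca[, 1], cb[, 1], `-`)^2 + outer(ca[, 2], cb[, 2], `-`)^2)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  idx_b <- seq_len(nb)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  for (p in perms(idx_b)) {
    pairs <- list(); cost <- 0
    for (i in seq_len(min(na, nb))) {
      if (D[i, p[i]] <= max_distance) {
        pairs[[length(pairs) + 1L]] <- c(i, p[i])
        cost <- cost + D[i, p[i]]
      }
    }
    n <- length(pairs)
    if (n > best_n || (n == best_n && cost < best_cost)) {
      best <- pairs; best_cost <- cost; best_n <- n
    }
  }
  best
}

tiny_sample <- function(dims = c(64, 64), count = 3, seed = 1,
                        area = c(10, 60)) {
  spec <- cohort_spec(image_dims = dims, pigment_area_range = area,
                      seed = seed)
  set.seed(seed)
  generate_fundus(spec, pigment_count = count)
}

tiny_net <- function(widths = c(2L, 3L, 4L, 5L), rows = 16L, cols = 16L,
                     seed = 1) {
  build_network(rps_spec(input_rows = rows, input_cols = cols,
                         block_widths = widths), seed = seed)
}
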