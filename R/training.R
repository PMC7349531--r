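#' Per-class pixel frequencies over a set of masks
#'
#' The frequency of class c is the number of pixels of class c divided by
#' the total pixel count of only those images in which class c appears —
#' the convention used by median-frequency balancing.
#'
#' @param masks List of binary masks (0 = background, 1 = pigment), or a
#'   single mask.
#' @return Named numeric vector `c(background = ..., pigment = ...)`. A
#'   class absent from every mask gets frequency 0 (flagged with a warning).
#' @examples
#' m <- matrix(0L, 10, 10); m[1:2, 1:5] <- 1L
#' class_frequencies(list(m))  # 0.9 / 0.1
#' @export
class_frequencies <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  counts <- c(background = 0, pigment = 0)
  denom <- c(background = 0, pigment = 0)
  for (m in masks) {
    npix <- length(m)
    n1 <- sum(m == 1L)
    n0 <- npix - n1
    if (n0 > 0) { counts[1] <- counts[1] + n0; denom[1] <- denom[1] + npix }
    if (n1 > 0) { counts[2] <- counts[2] + n1; denom[2] <- denom[2] + npix }
  }
  freq <- ifelse(denom > 0, counts / denom, 0)
  if (any(freq == 0))
    warning("class absent from every mask: ",
            paste(names(freq)[freq == 0], collapse = ", "), call. = FALSE)
  freq
}

#' Median-frequency class weights
#'
#' weight(c) = median(frequencies) / frequency(c), so rare classes are
#' up-weighted in the pixel loss. For two classes the median is the midpoint
#' of the two frequencies, making weight(c) * freq(c) constant across c.
#'
#' @param freqs Named per-class frequency vector (all > 0).
#' @return Named positive weight vector.
#' @examples
#' median_frequency_weights(c(background = 0.9, pigment = 0.1))
#' @export
median_frequency_weights <- function(freqs) {
  if (any(freqs <= 0))
    stop("all class frequencies must be > 0; exclude the class or floor ",
         "frequencies at a small epsilon before weighting", call. = FALSE)
  stats::median(freqs) / freqs
}

#' Weighted per-pixel cross-entropy
#'
#' Mean over pixels of weight(true class) * (-log p(true class)).
#' Probabilities below 1e-12 are floored before the log.
#'
#' @param probabilities rows x cols x n_classes array, normalized per pixel.
#' @param mask rows x cols integer labels in 0..(n_classes-1).
#' @param weights Per-class positive weights (index 1 = class 0).
#' @return Scalar loss (non-negative).
#' @export
weighted_pixel_loss <- function(probabilities, mask, weights) {
  d <- dim(probabilities)
  stopifnot(length(d) == 3, all(dim(mask) == d[1:2]))
  idx <- cbind(c(row(mask)), c(col(mask)), c(mask) + 1L)
  p <- pmax(probabilities[idx], 1e-12)
  mean(weights[c(mask) + 1L] * (-log(p)))
}

#' Patient-wise k-fold split
#'
#' Each fold holds out every sample of one patient group; training and test
#' sides never share a patient, so evaluation measures generalization to an
#' unseen patient (the cross-validation protocol for the cohort).
#'
#' @param samples List of `fundus_sample` objects (with `$patient_id`).
#' @param k Number of folds (default 4; must not exceed the number of
#'   distinct patients).
#' @return List of k elements, each `list(train, test)` of sample lists.
#' @export
patient_kfold <- function(samples, k = 4L) {
  ids <- vapply(samples, function(s) s$patient_id, "")
  pats <- unique(ids)
  if (k > length(pats))
    stop("k = ", k, " exceeds the number of distinct patients (",
         length(pats), ")", call. = FALSE)
  groups <- split(seq_along(pats), rep_len(seq_len(k), length(pats)))
  lapply(groups, function(g) {
    held <- pats[g]
    list(train = samples[!(ids %in% held)], test = samples[ids %in% held])
  })
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam with constant learning rate
#' 1e-4 and epsilon 1e-6, minibatches of 10 images, 20 epochs, reshuffling
#' each epoch. `clip_norm` optionally rescales the global L2 norm of the
#' gradient to at most the given threshold (off by default).
#'
#' @param learning_rate Positive step size.
#' @param adam_epsilon Adam denominator epsilon.
#' @param epochs Number of passes over the training set.
#' @param minibatch Images per iteration.
#' @param shuffle_each_epoch Reshuffle sample order every epoch?
#' @param clip_norm Optional global-L2 gradient clipping threshold.
#' @param seed Integer seed controlling shuffling (and any weight init done
#'   by the caller).
#' @return An object of class `rps_train_config`.
#' @export
rps_train_config <- function(learning_rate = 1e-4, adam_epsilon = 1e-6,
                             epochs = 20L, minibatch = 10L,
                             shuffle_each_epoch = TRUE, clip_norm = NULL,
                             seed = 1L) {
  stopifnot(learning_rate > 0, minibatch >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, adam_epsilon = adam_epsilon,
                 epochs = as.integer(epochs), minibatch = as.integer(minibatch),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "rps_train_config")
}

# Map over every parameter leaf of two parallel nested lists.
.param_map <- function(a, b, f)
  Map(function(pa, pb) Map(f, pa, pb), a, b)

.global_norm <- function(grads)
  sqrt(sum(vapply(grads, function(g) sum(vapply(g, function(x) sum(x^2), 0)),
                  0)))

#' Train the network
#'
#' Minimizes the median-frequency-weighted per-pixel cross-entropy with
#' Adam. Images are scaled to [0, 1]; the per-pixel softmax output is
#' compared against the sample masks. Deterministic given
#' `config$seed`.
#'
#' @param net An `rps_network` (updated weights are returned, R-semantics).
#' @param train_samples List of `fundus_sample` objects.
#' @param config An `rps_train_config`.
#' @param class_weights Optional per-class loss weights; by default computed
#'   by median-frequency balancing on `train_samples`' masks.
#' @param verbose Print per-epoch mean loss?
#' @return List: `net` (trained), `history` (data.frame with iteration,
#'   epoch, loss), `class_weights`.
#' @export
train_network <- function(net, train_samples, config = rps_train_config(),
                          class_weights = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "rps_network"), inherits(config, "rps_train_config"))
  if (length(train_samples) == 0) stop("no training samples", call. = FALSE)
  if (is.null(class_weights)) {
    freqs <- class_frequencies(lapply(train_samples, `[[`, "mask"))
    class_weights <- median_frequency_weights(pmax(freqs, 1e-8))
  }
  xs_all <- lapply(train_samples, function(s) s$image / 255)
  ys_all <- lapply(train_samples, `[[`, "mask")
  n <- length(xs_all)
  m <- rapply(net$params, function(x) x * 0, how = "replace")
  v <- m
  t_step <- 0L
  history <- list()
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  b1 <- 0.9; b2 <- 0.999
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle_each_epoch || epoch == 1L) sample.int(n)
           else seq_len(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$minibatch))
    for (bt in batches) {
      xs <- xs_all[bt]; ys <- ys_all[bt]
      fw <- .forward_batch(net, xs, keep_cache = TRUE)
      npix_tot <- sum(vapply(ys, length, 0L))
      loss <- 0
      glog <- Map(function(p, y) {
        d <- dim(p)
        wpix <- class_weights[c(y) + 1L]
        idx <- cbind(c(row(y)), c(col(y)), c(y) + 1L)
        loss <<- loss + sum(wpix * (-log(pmax(p[idx], 1e-12))))
        g <- p
        g[idx] <- g[idx] - 1
        g * array(rep(wpix, d[3]), dim = d) / npix_tot
      }, fw$probs, ys)
      loss <- loss / npix_tot
      if (!is.finite(loss))
        stop("non-finite loss at iteration ", t_step + 1L,
             " (epoch ", epoch, "); lower the learning rate", call. = FALSE)
      grads <- .backward_batch(net, fw$cache, glog)
      grads <- grads[names(net$params)]
      if (!is.null(config$clip_norm)) {
        gn <- .global_norm(grads)
        if (gn > config$clip_norm)
          grads <- rapply(grads, function(g) g * config$clip_norm / gn,
                          how = "replace")
      }
      t_step <- t_step + 1L
      m <- .param_map(m, grads, function(mm, g) b1 * mm + (1 - b1) * g)
      v <- .param_map(v, grads, function(vv, g) b2 * vv + (1 - b2) * g^2)
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      net$params <- .param_map(net$params, .param_map(m, v, function(mm, vv)
        (mm / corr1) / (sqrt(vv / corr2) + config$adam_epsilon)),
        function(p, upd) p - config$learning_rate * upd)
      history[[t_step]] <- data.frame(iteration = t_step, epoch = epoch,
                                      loss = loss)
    }
    if (verbose) {
      ep_loss <- mean(vapply(history[vapply(history, function(h)
        h$epoch == epoch, TRUE)], function(h) h$loss, 0))
      message(sprintf("epoch %d/%d  mean loss %.5f", epoch, config$epochs,
                      ep_loss))
    }
  }
  list(net = net, history = do.call(rbind, history),
       class_weights = class_weights)
}

#' Predict a binary pigment mask
#'
#' @param net Trained `rps_network`.
#' @param image rows x cols x 3 array, 0-255 intensity scale.
#' @param threshold Pigment-probability threshold (0.5 = per-pixel argmax
#'   for two classes).
#' @return List: `prob` (pigment-class probability matrix), `mask` (binary
#'   integer matrix).
#' @export
predict_mask <- function(net, image, threshold = 0.5) {
  pr <- network_forward(net, image / 255)
  pig <- pr[, , net$spec$n_classes]
  list(prob = pig, mask = matrix(as.integer(pig >= threshold), nrow(pig)))
}

#' Save / load network checkpoints
#'
#' Serializes the spec and weights with R's native serialization.
#'
#' @param net An `rps_network`.
#' @param path Checkpoint file path (.rds).
#' @return `load_checkpoint` returns the `rps_network`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "rps_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "rps_network"))
  net
}
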