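#' Pixel-level confusion counts
#'
#' TP: pigment in truth, predicted pigment. FN: pigment in truth, predicted
#' background. FP: background in truth, predicted pigment. TN: background
#' in both.
#'
#' @param predicted_mask,truth_mask Binary matrices of equal dims.
#' @return Object of class `confusion_counts` (named list TP, FN, FP, TN).
#' @export
confusion_counts <- function(predicted_mask, truth_mask) {
  if (!all(dim(predicted_mask) == dim(truth_mask)))
    stop("predicted and truth masks have different dimensions",
         call. = FALSE)
  p <- predicted_mask == 1L
  t <- truth_mask == 1L
  structure(list(TP = sum(p & t), FN = sum(!p & t),
                 FP = sum(p & !t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' Add confusion counts (micro-average pooling)
#' @param a,b `confusion_counts`.
#' @return Their elementwise sum.
#' @export
add_counts <- function(a, b)
  structure(list(TP = a$TP + b$TP, FN = a$FN + b$FN,
                 FP = a$FP + b$FP, TN = a$TN + b$TN),
            class = "confusion_counts")

#' Segmentation metrics from confusion counts
#'
#' Sen = TP/(TP+FN), Spe = TN/(TN+FP), P = TP/(TP+FP),
#' Acc = (TP+TN)/total, F = 2TP/(2TP+FP+FN). A 0/0 denominator yields 0
#' and sets the `degenerate` flag (e.g. a healthy image with an empty
#' prediction).
#'
#' @param counts A `confusion_counts`.
#' @return Object of class `metrics_report`: Sen, Spe, P, Acc, F in [0,1]
#'   plus `degenerate` (character vector of flagged metrics).
#' @examples
#' compute_metrics(structure(list(TP = 8, FN = 2, FP = 2, TN = 88),
#'                           class = "confusion_counts"))
#' @export
compute_metrics <- function(counts) {
  tot <- counts$TP + counts$FN + counts$FP + counts$TN
  if (tot == 0) stop("no pixels evaluated", call. = FALSE)
  flags <- character()
  safe <- function(num, den, nm) {
    if (den == 0) { flags <<- c(flags, nm); return(0) }
    num / den
  }
  out <- list(
    Sen = safe(counts$TP, counts$TP + counts$FN, "Sen"),
    Spe = safe(counts$TN, counts$TN + counts$FP, "Spe"),
    P = safe(counts$TP, counts$TP + counts$FP, "P"),
    Acc = (counts$TP + counts$TN) / tot,
    F = safe(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN, "F"))
  out$degenerate <- flags
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sen %.2f%%  Spe %.2f%%  P %.2f%%  Acc %.2f%%  F %.2f%%\n",
              100 * x$Sen, 100 * x$Spe, 100 * x$P, 100 * x$Acc, 100 * x$F))
  if (length(x$degenerate))
    cat("degenerate (0/0 -> 0):", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Pixel-pooled ROC curve, AUC and equal-error-rate point
#'
#' Sweeps a threshold over the pigment-class probability pooled over all
#' pixels of all images, tracing (1 - Spe, Sen). AUC by the trapezoidal
#' rule; the EER point (where Sen = Spe) by linear interpolation along the
#' sweep.
#'
#' @param probability_maps List of pigment-probability matrices (or one
#'   matrix).
#' @param truth_masks List of matching binary masks (or one matrix).
#' @param n_thresholds Number of evenly spaced thresholds in [0, 1].
#' @return Object of class `roc_curve`: data.frame `points`
#'   (threshold, fpr, sen, spe), `auc`, `eer` (list: threshold, sen, spe).
#' @export
roc_and_auc <- function(probability_maps, truth_masks, n_thresholds = 101L) {
  if (is.matrix(probability_maps)) probability_maps <- list(probability_maps)
  if (is.matrix(truth_masks)) truth_masks <- list(truth_masks)
  p <- unlist(lapply(probability_maps, as.numeric))
  y <- unlist(lapply(truth_masks, as.numeric))
  if (any(p < 0 | p > 1)) stop("probabilities outside [0,1]", call. = FALSE)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    stop("ground truth contains a single class; ROC undefined",
         call. = FALSE)
  th <- seq(0, 1, length.out = n_thresholds)
  # predicted pigment: p >= threshold; counts via sorted probabilities
  pos_sorted <- sort(p[y == 1])
  neg_sorted <- sort(p[y == 0])
  tp <- npos - findInterval(th, pos_sorted, left.open = TRUE)
  fp <- nneg - findInterval(th, neg_sorted, left.open = TRUE)
  sen <- tp / npos
  spe <- (nneg - fp) / nneg
  fpr <- 1 - spe
  ord <- order(fpr, sen)
  auc <- sum(diff(fpr[ord]) * (utils::head(sen[ord], -1) +
                                 utils::tail(sen[ord], -1)) / 2)
  d <- sen - spe
  ix <- which(diff(sign(d)) != 0)
  eer <- if (length(ix) == 0) {
    j <- which.min(abs(d))
    list(threshold = th[j], sen = sen[j], spe = spe[j])
  } else {
    i1 <- ix[1]; i2 <- i1 + 1L
    w <- if (d[i2] == d[i1]) 0 else d[i1] / (d[i1] - d[i2])
    list(threshold = th[i1] + w * (th[i2] - th[i1]),
         sen = sen[i1] + w * (sen[i2] - sen[i1]),
         spe = spe[i1] + w * (spe[i2] - spe[i1]))
  }
  structure(list(points = data.frame(threshold = th, fpr = fpr, sen = sen,
                                     spe = spe),
                 auc = auc, eer = eer),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("pixel ROC: AUC %.5f, EER at threshold %.3f (Sen %.3f)\n",
              x$auc, x$eer$threshold, x$eer$sen))
  invisible(x)
}

#' Upscale a probability map by bilinear interpolation
#'
#' Used to score low-resolution predictions against native-resolution
#' ground truth: the pigment-probability map is interpolated first and
#' thresholded afterwards, so mask values never leave {0, 1}.
#'
#' @param probability_map Numeric matrix in [0, 1].
#' @param target_dims `c(rows, cols)`.
#' @return Matrix of the target size, values clamped to [0, 1].
#' @export
upscale_prediction <- function(probability_map, target_dims) {
  stopifnot(all(target_dims > 0))
  if (all(dim(probability_map) == target_dims)) return(probability_map)
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(t(probability_map)),
    w = target_dims[2], h = target_dims[1]))
  pmin(pmax(t(out), 0), 1)
}

#' Evaluate a trained network on a held-out fold
#'
#' Runs the network on every test sample, optionally upscales the pigment
#' probability to the native mask resolution, thresholds, pools the pixel
#' confusion counts over the fold (micro-average) and builds the pooled
#' ROC curve.
#'
#' @param net Trained `rps_network`.
#' @param test_samples List of `fundus_sample` with masks from the grader
#'   being scored.
#' @param native_masks Optional list of native-resolution truth masks; when
#'   given, predictions are bilinearly upscaled to their size before
#'   thresholding and scoring.
#' @param threshold Pigment-probability binarization threshold.
#' @param roc_at_native Compute the ROC at native resolution too? Default
#'   FALSE (training resolution).
#' @return List: `metrics` (pooled `metrics_report`), `counts`, `per_image`
#'   (data.frame of per-image metrics), `roc` (`roc_curve`).
#' @export
evaluate_fold <- function(net, test_samples, native_masks = NULL,
                          threshold = 0.5, roc_at_native = FALSE) {
  stopifnot(length(test_samples) > 0)
  if (!is.null(native_masks))
    stopifnot(length(native_masks) == length(test_samples))
  pooled <- structure(list(TP = 0, FN = 0, FP = 0, TN = 0),
                      class = "confusion_counts")
  per <- list()
  probs <- list(); truths <- list()
  for (i in seq_along(test_samples)) {
    s <- test_samples[[i]]
    pred <- predict_mask(net, s$image, threshold)
    prob <- pred$prob
    truth <- s$mask
    if (!is.null(native_masks)) {
      truth <- native_masks[[i]]
      prob <- upscale_prediction(prob, dim(truth))
    }
    pm <- matrix(as.integer(prob >= threshold), nrow(prob))
    cc <- confusion_counts(pm, truth)
    pooled <- add_counts(pooled, cc)
    mt <- compute_metrics(cc)
    per[[i]] <- data.frame(image = i, TP = cc$TP, FN = cc$FN, FP = cc$FP,
                           TN = cc$TN, Sen = mt$Sen, Spe = mt$Spe,
                           P = mt$P, Acc = mt$Acc, F = mt$F)
    if (roc_at_native || is.null(native_masks)) {
      probs[[i]] <- prob; truths[[i]] <- truth
    } else {
      probs[[i]] <- pred$prob; truths[[i]] <- s$mask
    }
  }
  roc <- tryCatch(roc_and_auc(probs, truths),
                  error = function(e) NULL)
  list(metrics = compute_metrics(pooled), counts = pooled,
       per_image = do.call(rbind, per), roc = roc)
}
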