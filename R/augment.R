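# Paired image/mask augmentation: flips and integer translations applied
# identically to image and mask. Positive dx shifts content toward higher
# column index (right), positive dy toward higher row index (down); vacated
# borders are zero-filled (black, matching fundus borders) and masks stay
# binary. Every output keeps a provenance record of its op chain.

.tag <- function(sample, op) {
  sample$provenance <- c(sample$provenance, op)
  sample
}

#' Horizontal / vertical flips of a sample
#'
#' `hflip` mirrors about the vertical axis (columns reversed), `vflip`
#' about the horizontal axis (rows reversed); image and mask move together.
#'
#' @param sample A `fundus_sample`.
#' @return The flipped `fundus_sample`.
#' @export
hflip <- function(sample) {
  sample$image <- sample$image[, ncol(sample$mask):1, , drop = FALSE]
  sample$mask <- sample$mask[, ncol(sample$mask):1, drop = FALSE]
  .tag(sample, "hflip")
}

#' @rdname hflip
#' @export
vflip <- function(sample) {
  sample$image <- sample$image[nrow(sample$mask):1, , , drop = FALSE]
  sample$mask <- sample$mask[nrow(sample$mask):1, , drop = FALSE]
  .tag(sample, "vflip")
}

.shift_matrix <- function(m, dx, dy, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  sr <- intersect(seq_len(nrow(m)) + dy, seq_len(nrow(m)))
  sc <- intersect(seq_len(ncol(m)) + dx, seq_len(ncol(m)))
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

#' Translate a sample by whole pixels
#'
#' @param sample A `fundus_sample`.
#' @param dx Columns to shift (positive = right).
#' @param dy Rows to shift (positive = down).
#' @return The shifted `fundus_sample` (zero-filled borders).
#' @export
translate <- function(sample, dx, dy) {
  stopifnot(abs(dx) < ncol(sample$mask), abs(dy) < nrow(sample$mask))
  for (ch in 1:3)
    sample$image[, , ch] <- .shift_matrix(sample$image[, , ch], dx, dy)
  sample$mask <- .shift_matrix(sample$mask, dx, dy)
  storage.mode(sample$mask) <- "integer"
  .tag(sample, sprintf("translate(%d,%d)", dx, dy))
}

#' The default four-stage augmentation plan
#'
#' Stage 1 adds a horizontal and a vertical flip of every input (x3);
#' stage 2 adds a (+5, -5) translation of everything so far (x2); stage 3
#' adds a (-5, +5) translation combined with a horizontal flip (x2);
#' stage 4 adds a (+10, +10) translation combined with a vertical flip
#' (x2). Net expansion x24: 90 inputs become 270, 540, 1080, 2160.
#'
#' @return List of stage descriptors consumed by [build_augmented_set()].
#' @export
default_augmentation_plan <- function() {
  list(
    list(ops = list(hflip, vflip), mode = "add_each"),
    list(ops = list(function(s) translate(s, 5L, -5L)), mode = "add_chain"),
    list(ops = list(function(s) hflip(translate(s, -5L, 5L))),
         mode = "add_chain"),
    list(ops = list(function(s) vflip(translate(s, 10L, 10L))),
         mode = "add_chain"))
}

#' Expand a training set through the augmentation cascade
#'
#' Each stage appends transformed copies of every sample accumulated so
#' far, keeping the originals ("add_each": one copy per listed op;
#' "add_chain": one copy through the composed op).
#'
#' @param samples Non-empty list of `fundus_sample`.
#' @param plan Augmentation plan (default [default_augmentation_plan()]).
#' @param stage_counts Also return the cumulative count after each stage?
#' @return The augmented sample list; with `stage_counts = TRUE`, a list
#'   `(samples, counts)`.
#' @examples
#' set.seed(1)
#' s <- generate_fundus(cohort_spec(image_dims = c(64, 64)), 2)
#' length(build_augmented_set(list(s)))  # 24
#' @export
build_augmented_set <- function(samples, plan = default_augmentation_plan(),
                                stage_counts = FALSE) {
  if (length(samples) == 0) stop("empty input sample list", call. = FALSE)
  acc <- samples
  counts <- integer(length(plan))
  for (k in seq_along(plan)) {
    stage <- plan[[k]]
    new <- list()
    for (op in stage$ops) new <- c(new, lapply(acc, op))
    acc <- c(acc, new)
    counts[k] <- length(acc)
  }
  if (stage_counts) list(samples = acc, counts = counts) else acc
}
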