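# Dataset I/O. Layout: <root>/<patient>/<eye>_<session>_<index>.png with
# sibling masks <stem>_<grader>.png, plus a manifest.csv
# (path, patient, session, eye, grader). Masks are binarized at 128 on load.

#' Save an image/mask dataset
#'
#' Writes each sample as a PNG pair under a per-patient directory and a
#' `manifest.csv` indexing the files.
#'
#' @param samples List of `fundus_sample` objects.
#' @param root_path Output directory (created if missing).
#' @param grader Mask suffix to write under (default the samples' own
#'   grader tag).
#' @return Invisibly, the manifest data.frame.
#' @export
save_dataset <- function(samples, root_path, grader = NULL) {
  dir.create(root_path, showWarnings = FALSE, recursive = TRUE)
  counter <- new.env(parent = emptyenv())
  rows <- lapply(samples, function(s) {
    g <- if (is.null(grader)) s$grader else grader
    key <- paste(s$patient_id, s$eye, s$session, sep = "_")
    n <- (if (is.null(counter[[key]])) 0L else counter[[key]]) + 1L
    counter[[key]] <- n
    dir.create(file.path(root_path, s$patient_id), showWarnings = FALSE)
    stem <- sprintf("%s_%d_%d", s$eye, s$session, n)
    ipath <- file.path(s$patient_id, paste0(stem, ".png"))
    mpath <- file.path(s$patient_id, sprintf("%s_%s.png", stem, g))
    png::writePNG(aperm(s$image, c(1, 2, 3)) / 255,
                  file.path(root_path, ipath))
    png::writePNG(s$mask * 1.0, file.path(root_path, mpath))
    data.frame(path = ipath, mask_path = mpath, patient = s$patient_id,
               session = s$session, eye = s$eye, grader = g)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root_path, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

.read_image_255 <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

.resize_sample <- function(image, mask, dims) {
  # bilinear for intensities, nearest-neighbour for labels (label-safe)
  img <- EBImage::resize(EBImage::Image(aperm(image, c(2, 1, 3)) / 255,
                                        colormode = "Color"),
                         w = dims[2], h = dims[1])
  msk <- EBImage::resize(EBImage::Image(t(mask * 1.0)),
                         w = dims[2], h = dims[1], filter = "none")
  list(image = aperm(EBImage::imageData(img), c(2, 1, 3)) * 255,
       mask = matrix(as.integer(t(EBImage::imageData(msk)) >= 0.5),
                     dims[1], dims[2]))
}

#' Load an image/mask dataset
#'
#' Reads the `manifest.csv` written by [save_dataset()] (or scans for PNG
#' pairs when absent). Masks are binarized at intensity 128. An image with
#' no mask is skipped with a warning in `mode = "training"` and is an error
#' in `mode = "evaluation"`.
#'
#' @param root_path Dataset directory.
#' @param grader Which grader's masks to load (default: whatever the
#'   manifest lists).
#' @param resize_to Optional `c(rows, cols)`: bilinear resize for images,
#'   nearest-neighbor for masks (mask values stay binary).
#' @param mode "training" or "evaluation".
#' @return List of `fundus_sample`.
#' @export
load_dataset <- function(root_path, grader = NULL, resize_to = NULL,
                         mode = c("training", "evaluation")) {
  mode <- match.arg(mode)
  mfile <- file.path(root_path, "manifest.csv")
  if (file.exists(mfile)) {
    manifest <- utils::read.csv(mfile, stringsAsFactors = FALSE)
  } else {
    imgs <- list.files(root_path, pattern = "\\.png$", recursive = TRUE)
    is_mask <- grepl("_(G1|G2|synthetic)\\.png$", imgs)
    manifest <- data.frame(path = imgs[!is_mask])
    manifest$patient <- dirname(manifest$path)
    parts <- strsplit(sub("\\.png$", "", basename(manifest$path)), "_")
    manifest$eye <- vapply(parts, `[`, "", 1)
    manifest$session <- as.integer(vapply(parts, `[`, "", 2))
    g <- if (is.null(grader)) "synthetic" else grader
    manifest$mask_path <- sub("\\.png$", sprintf("_%s.png", g),
                              manifest$path)
    manifest$grader <- g
  }
  if (!is.null(grader))
    manifest$mask_path <- sub("_(G1|G2|synthetic)\\.png$",
                              sprintf("_%s.png", grader),
                              manifest$mask_path)
  samples <- list()
  for (r in seq_len(nrow(manifest))) {
    ip <- file.path(root_path, manifest$path[r])
    mp <- file.path(root_path, manifest$mask_path[r])
    if (!file.exists(mp)) {
      if (mode == "evaluation")
        stop("mask missing for ", manifest$path[r], call. = FALSE)
      warning("mask missing for ", manifest$path[r], "; skipped",
              call. = FALSE)
      next
    }
    img <- .read_image_255(ip)
    mraw <- png::readPNG(mp)
    if (length(dim(mraw)) == 3) mraw <- mraw[, , 1]
    if (!all(dim(img)[1:2] == dim(mraw)))
      stop("image/mask dimension mismatch for ", manifest$path[r],
           call. = FALSE)
    mask <- matrix(as.integer(mraw * 255 >= 128), nrow(mraw), ncol(mraw))
    if (!is.null(resize_to)) {
      rs <- .resize_sample(img, mask, resize_to)
      img <- rs$image; mask <- rs$mask
    }
    samples[[length(samples) + 1L]] <-
      fundus_sample(img, mask, patient_id = manifest$patient[r],
                    session = manifest$session[r], eye = manifest$eye[r],
                    grader = if (is.null(grader)) manifest$grader[r]
                             else grader)
  }
  samples
}
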