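# Synthetic fundus image generator. Emulates the statistical structure the
# segmentation task needs -- a bright circular retina field on dark corners,
# an optic-disc highlight, curved vessel strokes, and a handful of small
# dark pigment deposits occupying well under 5% of the pixels -- with exact
# ground-truth masks, grouped into synthetic patients for fold splitting.

#' Cohort specification for synthetic fundus data
#'
#' Defaults mirror the reference cohort layout: 4 patients, 30 images each
#' (5 images x 2 eyes x 3 sessions), 21 of the 120 images healthy
#' (empty masks), images of 400 x 300 pixels.
#'
#' @param n_patients Number of synthetic patients.
#' @param images_per_patient Images per patient.
#' @param healthy_fraction Fraction of images with no pigment signs.
#' @param image_dims `c(rows, cols)` of generated images.
#' @param pigment_count_range `c(min, max)` pigment deposits per diseased
#'   image.
#' @param pigment_area_range `c(min, max)` pixels per deposit.
#' @param seed Integer seed making the cohort reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 4L, images_per_patient = 30L,
                        healthy_fraction = 21 / 120,
                        image_dims = c(400L, 300L),
                        pigment_count_range = c(2L, 8L),
                        pigment_area_range = c(10L, 200L),
                        seed = 1L) {
  stopifnot(n_patients >= 1, images_per_patient >= 1,
            healthy_fraction >= 0, healthy_fraction <= 1,
            all(pigment_area_range > 0), all(image_dims >= 32))
  structure(list(n_patients = as.integer(n_patients),
                 images_per_patient = as.integer(images_per_patient),
                 healthy_fraction = healthy_fraction,
                 image_dims = as.integer(image_dims),
                 pigment_count_range = as.integer(pigment_count_range),
                 pigment_area_range = as.integer(pigment_area_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' A fundus image / mask pair with acquisition metadata
#'
#' @param image rows x cols x 3 numeric array, 0-255.
#' @param mask rows x cols integer matrix, 0 = background, 1 = pigment.
#' @param patient_id Patient identifier.
#' @param session Imaging session (1-3).
#' @param eye "left" or "right".
#' @param grader Mask provenance: "G1", "G2" or "synthetic".
#' @return Object of class `fundus_sample`.
#' @export
fundus_sample <- function(image, mask, patient_id = "P1", session = 1L,
                          eye = "left", grader = "synthetic") {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            all(dim(image)[1:2] == dim(mask)),
            all(mask %in% c(0L, 1L)))
  structure(list(image = image, mask = mask,
                 patient_id = as.character(patient_id),
                 session = as.integer(session), eye = eye, grader = grader,
                 provenance = character()),
            class = "fundus_sample")
}

#' @export
print.fundus_sample <- function(x, ...) {
  cat(sprintf("fundus_sample %s/%s/session %d: %d x %d, %d pigment px\n",
              x$patient_id, x$eye, x$session, nrow(x$mask), ncol(x$mask),
              sum(x$mask)))
  invisible(x)
}

# Grow one irregular deposit by randomized accretion: start from a seed,
# repeatedly annex a uniformly chosen 4-neighbour of the current set that
# is inside the retina and outside the exclusion halo of earlier deposits.
.grow_blob <- function(rows, cols, seed_rc, area, allowed) {
  blob <- matrix(FALSE, rows, cols)
  blob[seed_rc[1], seed_rc[2]] <- TRUE
  frontier <- list()
  push_nb <- function(r, c) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nr <- r + d[1]; nc <- c + d[2]
      if (nr >= 1 && nr <= rows && nc >= 1 && nc <= cols &&
          !blob[nr, nc] && allowed[nr, nc])
        frontier[[length(frontier) + 1L]] <<- c(nr, nc)
    }
  }
  push_nb(seed_rc[1], seed_rc[2])
  n <- 1L
  while (n < area && length(frontier) > 0) {
    k <- sample.int(length(frontier), 1L)
    px <- frontier[[k]]
    frontier[[k]] <- frontier[[length(frontier)]]
    frontier[[length(frontier)]] <- NULL
    if (blob[px[1], px[2]]) next
    blob[px[1], px[2]] <- TRUE
    n <- n + 1L
    push_nb(px[1], px[2])
  }
  blob
}

.smooth_noise <- function(rows, cols, scale, amp) {
  ph <- stats::runif(4, 0, 2 * pi)
  fr <- stats::runif(2, 0.5, 1.5) * scale
  outer(sin(fr[1] * seq_len(rows) / rows * 2 * pi + ph[1]),
        cos(fr[2] * seq_len(cols) / cols * 2 * pi + ph[2])) * amp +
    outer(cos(2.3 * fr[1] * seq_len(rows) / rows * 2 * pi + ph[3]),
          sin(1.7 * fr[2] * seq_len(cols) / cols * 2 * pi + ph[4])) * amp / 2
}

#' Generate one synthetic fundus image with an exact pigment mask
#'
#' Draws from the current RNG state; seed beforehand (or through
#' [generate_cohort()]) for reproducibility.
#'
#' @param spec A [cohort_spec()] (image dims and pigment ranges are used).
#' @param pigment_count Number of deposits; `NULL` draws uniformly from
#'   `spec$pigment_count_range`, 0 yields a healthy image (empty mask).
#' @param appearance Optional list of per-patient appearance parameters:
#'   `tint` (added to the red channel), `vessel_n` (vessel count).
#' @return A `fundus_sample` (grader "synthetic").
#' @examples
#' set.seed(7)
#' s <- generate_fundus(cohort_spec(image_dims = c(64, 64)), pigment_count = 3)
#' sum(s$mask)  # exact pigment pixel count
#' @export
generate_fundus <- function(spec, pigment_count = NULL, appearance = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- spec$image_dims[1]; cols <- spec$image_dims[2]
  amax <- spec$pigment_area_range[2]
  if (amax * 9 > rows * cols)
    stop("pigment areas incompatible with image size", call. = FALSE)
  if (is.null(pigment_count))
    pigment_count <- sample(spec$pigment_count_range[1]:
                              spec$pigment_count_range[2], 1L)
  tint <- if (is.null(appearance$tint)) 0 else appearance$tint
  vessel_n <- if (is.null(appearance$vessel_n)) 6L else appearance$vessel_n

  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  rad <- 0.48 * min(rows, cols)
  dist2 <- outer((seq_len(rows) - cy)^2, (seq_len(cols) - cx)^2, `+`)
  field <- dist2 <= rad^2
  falloff <- pmax(1 - sqrt(dist2) / (1.25 * rad), 0)

  R <- matrix(8, rows, cols); G <- matrix(6, rows, cols)
  B <- matrix(5, rows, cols)
  tex <- .smooth_noise(rows, cols, 3, 12)
  R[field] <- (175 + tint + tex + 40 * falloff)[field]
  G[field] <- (85 + 0.5 * tex + 25 * falloff)[field]
  B[field] <- (38 + 0.3 * tex + 10 * falloff)[field]

  # optic disc: bright, slightly off-center
  ang <- stats::runif(1, 0, 2 * pi)
  dc <- c(cy + 0.45 * rad * sin(ang), cx + 0.45 * rad * cos(ang))
  drad <- 0.16 * rad
  disc <- outer((seq_len(rows) - dc[1])^2, (seq_len(cols) - dc[2])^2,
                `+`) <= drad^2
  R[disc] <- pmin(R[disc] + 70, 255); G[disc] <- pmin(G[disc] + 95, 255)
  B[disc] <- pmin(B[disc] + 80, 255)

  # vessels: darker quadratic arcs radiating from the disc center
  for (v in seq_len(vessel_n)) {
    th <- stats::runif(1, 0, 2 * pi)
    bend <- stats::runif(1, -0.8, 0.8)
    len <- stats::runif(1, 0.6, 1.1) * rad
    tseq <- seq(0, 1, length.out = ceiling(2 * len))
    rr <- dc[1] + len * tseq * sin(th) + bend * rad * tseq^2 * cos(th)
    cc <- dc[2] + len * tseq * cos(th) - bend * rad * tseq^2 * sin(th)
    ok <- rr >= 2 & rr <= rows - 1 & cc >= 2 & cc <= cols - 1
    for (p in which(ok)) {
      ri <- round(rr[p]); ci <- round(cc[p])
      sel <- cbind(rep(ri + (-1:0), 2), rep(ci + (-1:0), each = 2))
      infield <- field[sel]
      sel <- sel[infield, , drop = FALSE]
      R[sel] <- R[sel] * 0.72; G[sel] <- G[sel] * 0.55
      B[sel] <- B[sel] * 0.55
    }
  }

  mask <- matrix(0L, rows, cols)
  if (pigment_count > 0) {
    # deposits must stay a rare class: cap the total pigment budget at 4%
    # of the image, scaling drawn areas down proportionally when needed
    amin <- spec$pigment_area_range[1]
    areas <- sample(amin:spec$pigment_area_range[2], pigment_count,
                    replace = TRUE)
    budget <- floor(0.04 * rows * cols)
    if (pigment_count * amin > budget)
      stop("pigment areas incompatible with image size", call. = FALSE)
    if (sum(areas) > budget) {
      areas <- pmax(amin, as.integer(floor(areas * budget / sum(areas))))
      while (sum(areas) > budget && any(areas > amin)) {
        adj <- areas > amin
        areas[adj] <- pmax(amin, areas[adj] -
                             ceiling((sum(areas) - budget) / sum(adj)))
      }
    }
    inner <- dist2 <= (0.88 * rad)^2 & !disc
    halo <- matrix(FALSE, rows, cols)  # 2-px exclusion around placed blobs
    placed <- 0L
    tries <- 0L
    while (placed < pigment_count) {
      tries <- tries + 1L
      if (tries > 200L * pigment_count)
        stop("pigment areas incompatible with image size",
             call. = FALSE)
      seed_rc <- c(sample.int(rows, 1L), sample.int(cols, 1L))
      if (!inner[seed_rc[1], seed_rc[2]] || halo[seed_rc[1], seed_rc[2]] ||
          mask[seed_rc[1], seed_rc[2]] == 1L) next
      area <- areas[placed + 1L]
      blob <- .grow_blob(rows, cols, seed_rc, area, inner & !halo)
      if (sum(blob) < area) next
      mask[blob] <- 1L
      idx <- which(blob, arr.ind = TRUE)
      for (dr in -2:2) for (dcl in -2:2) {
        rr2 <- idx[, 1] + dr; cc2 <- idx[, 2] + dcl
        keep <- rr2 >= 1 & rr2 <= rows & cc2 >= 1 & cc2 <= cols
        halo[cbind(rr2[keep], cc2[keep])] <- TRUE
      }
      placed <- placed + 1L
    }
    dark <- stats::runif(sum(mask), 0.12, 0.25)
    R[mask == 1L] <- R[mask == 1L] * dark
    G[mask == 1L] <- G[mask == 1L] * dark
    B[mask == 1L] <- B[mask == 1L] * dark
  }

  img <- array(0, dim = c(rows, cols, 3))
  img[, , 1] <- pmin(pmax(R, 0), 255)
  img[, , 2] <- pmin(pmax(G, 0), 255)
  img[, , 3] <- pmin(pmax(B, 0), 255)
  fundus_sample(img, mask)
}

#' Generate a synthetic patient cohort
#'
#' Produces `n_patients * images_per_patient` samples. The healthy fraction
#' (empty masks) is honored exactly (deterministic rounding, spread across
#' patients); each patient gets its own appearance parameters (red-channel
#' tint, vessel density) so folds are distribution-shifted the way real
#' patients are.
#'
#' @param spec A [cohort_spec()].
#' @return List of `fundus_sample`, ordered by patient.
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 2, images_per_patient = 3,
#'                                   image_dims = c(64, 64), seed = 3))
#' table(vapply(co, function(s) s$patient_id, ""))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  total <- spec$n_patients * spec$images_per_patient
  n_healthy <- round(spec$healthy_fraction * total)
  base <- n_healthy %/% spec$n_patients
  extra <- n_healthy %% spec$n_patients
  per_pat_healthy <- base + as.integer(seq_len(spec$n_patients) <= extra)
  samples <- vector("list", total)
  k <- 0L
  for (p in seq_len(spec$n_patients)) {
    app <- list(tint = 10 * (p - 1) + stats::runif(1, -2, 2),
                vessel_n = 4L + 2L * ((p - 1L) %% 3L))
    healthy_idx <- seq_len(per_pat_healthy[p])  # first images of the patient
    for (i in seq_len(spec$images_per_patient)) {
      cnt <- if (i %in% healthy_idx) 0L else NULL
      s <- generate_fundus(spec, pigment_count = cnt, appearance = app)
      s$patient_id <- sprintf("P%d", p)
      s$session <- ((i - 1L) %/% (spec$images_per_patient / 3)) %% 3L + 1L
      s$eye <- if (i %% 2L == 0L) "right" else "left"
      k <- k + 1L
      samples[[k]] <- s
    }
  }
  samples
}
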