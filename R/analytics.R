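# Quantification of segmented pigment signs: connected-component labeling
# (8-connectivity -- deposits are irregular and diagonal strands must not
# split), per-region area / centroid / bounding box, pairwise centroid
# distances, and visit-to-visit matching for progression analysis.
# Coordinates are 0-based with x = column, y = row.

#' Label pigment regions in a binary mask
#'
#' Connected components under 8-connectivity. Regions are ordered by area
#' (descending), ties broken by bounding-box top-left corner.
#'
#' @param mask Binary integer matrix (1 = pigment).
#' @return List of `pigment_region`: `region_id`, `area`, `centroid`
#'   (named x, y; 0-based, x = column), `bounding_box` (row_min, col_min,
#'   row_max, col_max; 0-based).
#' @examples
#' m <- matrix(0L, 10, 10); m[2:5, 3:8] <- 1L
#' label_regions(m)[[1]]$area  # 24
#' @export
label_regions <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  lab <- .label_components8(matrix(as.integer(mask), nrow(mask)))
  n <- max(lab)
  if (n == 0) return(list())
  regions <- vector("list", n)
  for (k in seq_len(n)) {
    px <- which(lab == k, arr.ind = TRUE)  # 1-based (row, col)
    regions[[k]] <- structure(list(
      region_id = k,
      area = nrow(px),
      centroid = c(x = mean(px[, 2]) - 1, y = mean(px[, 1]) - 1),
      bounding_box = c(row_min = min(px[, 1]) - 1L,
                       col_min = min(px[, 2]) - 1L,
                       row_max = max(px[, 1]) - 1L,
                       col_max = max(px[, 2]) - 1L)),
      class = "pigment_region")
  }
  areas <- vapply(regions, `[[`, 0L, "area")
  rmin <- vapply(regions, function(r) r$bounding_box[["row_min"]], 0L)
  cmin <- vapply(regions, function(r) r$bounding_box[["col_min"]], 0L)
  ord <- order(-areas, rmin, cmin)
  regions <- regions[ord]
  for (k in seq_along(regions)) regions[[k]]$region_id <- k
  regions
}

#' Pairwise centroid distances
#'
#' @param regions List of `pigment_region`.
#' @return Symmetric matrix of Euclidean centroid distances in pixels
#'   (zero diagonal).
#' @export
centroid_distances <- function(regions) {
  stopifnot(length(regions) >= 1)
  xy <- t(vapply(regions, `[[`, c(x = 0, y = 0), "centroid"))
  as.matrix(stats::dist(xy))
}

#' Full pigment quantification report for one mask
#'
#' Regions (count, size, location) plus the pairwise centroid distance
#' matrix -- the measurements used to follow pigment deposits across
#' patient visits.
#'
#' @param mask Binary mask.
#' @param image_id Identifier recorded in the report.
#' @return Object of class `pigment_report`: `image_id`, `image_dims`,
#'   `count`, `regions`, `distances`.
#' @export
pigment_report <- function(mask, image_id = "image") {
  regions <- label_regions(mask)
  dm <- if (length(regions)) centroid_distances(regions)
        else matrix(numeric(), 0, 0)
  structure(list(image_id = image_id, image_dims = dim(mask),
                 count = length(regions), regions = regions,
                 distances = dm),
            class = "pigment_report")
}

#' @export
print.pigment_report <- function(x, ...) {
  cat(sprintf("pigment report %s: %d region(s)\n", x$image_id, x$count))
  for (r in x$regions)
    cat(sprintf("  #%d area %d px, centroid (x %.4f, y %.4f)\n",
                r$region_id, r$area, r$centroid[["x"]], r$centroid[["y"]]))
  invisible(x)
}

#' Serialize / deserialize a pigment report as JSON
#' @param report A `pigment_report`.
#' @param path Optional file; when NULL the JSON string is returned.
#' @return `report_to_json`: JSON (invisibly if written to file);
#'   `report_from_json`: the `pigment_report`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pigment_report"))
  obj <- list(image_id = report$image_id, image_dims = report$image_dims,
              count = report$count,
              regions = lapply(report$regions, function(r)
                list(region_id = r$region_id, area = r$area,
                     centroid = as.list(r$centroid),
                     bounding_box = as.list(r$bounding_box))),
              distances = report$distances)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  obj <- jsonlite::fromJSON(if (file.exists(path)) paste(readLines(path),
                                                         collapse = "")
                            else path, simplifyDataFrame = FALSE)
  regions <- lapply(obj$regions, function(r)
    structure(list(region_id = r$region_id, area = r$area,
                   centroid = unlist(r$centroid),
                   bounding_box = unlist(r$bounding_box)),
              class = "pigment_region"))
  dm <- if (obj$count > 0) matrix(unlist(obj$distances), obj$count,
                                  obj$count)
        else matrix(numeric(), 0, 0)
  structure(list(image_id = obj$image_id,
                 image_dims = unlist(obj$image_dims), count = obj$count,
                 regions = regions, distances = dm),
            class = "pigment_report")
}

#' Match pigment regions between two visits
#'
#' Greedy nearest-centroid matching (closest pair first) within
#' `max_distance`; matched pairs report area change and centroid
#' displacement, unmatched regions are listed as appeared (only in visit
#' B) or disappeared (only in visit A).
#'
#' @param report_a,report_b `pigment_report`s from same-size images.
#' @param max_distance Matching radius in pixels.
#' @return List: `matched` (data.frame id_a, id_b, distance, area_a,
#'   area_b, area_delta, displacement), `appeared`, `disappeared`
#'   (integer region ids).
#' @export
compare_visits <- function(report_a, report_b, max_distance = 30) {
  stopifnot(inherits(report_a, "pigment_report"),
            inherits(report_b, "pigment_report"))
  if (!all(report_a$image_dims == report_b$image_dims))
    stop("reports come from images of different sizes", call. = FALSE)
  na <- report_a$count; nb <- report_b$count
  if (na == 0 || nb == 0)
    return(list(matched = data.frame(), appeared = seq_len(nb),
                disappeared = seq_len(na)))
  ca <- t(vapply(report_a$regions, `[[`, c(x = 0, y = 0), "centroid"))
  cb <- t(vapply(report_b$regions, `[[`, c(x = 0, y = 0), "centroid"))
  D <- sqrt(outer(ca[, 1], cb[, 1], `-`)^2 + outer(ca[, 2], cb[, 2], `-`)^2)
  matched <- list()
  free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
  repeat {
    Dm <- D
    Dm[!free_a, ] <- Inf; Dm[, !free_b] <- Inf
    if (all(!is.finite(Dm)) || min(Dm) > max_distance) break
    ij <- arrayInd(which.min(Dm), dim(Dm))
    i <- ij[1]; j <- ij[2]
    ra <- report_a$regions[[i]]; rb <- report_b$regions[[j]]
    matched[[length(matched) + 1L]] <- data.frame(
      id_a = i, id_b = j, distance = D[i, j],
      area_a = ra$area, area_b = rb$area,
      area_delta = rb$area - ra$area, displacement = D[i, j])
    free_a[i] <- FALSE; free_b[j] <- FALSE
  }
  list(matched = if (length(matched)) do.call(rbind, matched)
                 else data.frame(),
       appeared = which(free_b), disappeared = which(free_a))
}
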