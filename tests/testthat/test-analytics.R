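test_that("a solid rectangle labels as one region with exact geometry", {
  m <- matrix(0L, 10, 12)
  m[3:6, 4:9] <- 1L  # 4 x 6 = 24 pixels
  regs <- label_regions(m)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$area, 24L)
  expect_equal(regs[[1]]$centroid, c(x = mean(3:8), y = mean(2:5)))
  expect_equal(unname(regs[[1]]$bounding_box), c(2L, 3L, 5L, 8L))
  expect_length(label_regions(matrix(0L, 5, 5)), 0)
})

test_that("diagonal neighbours join under 8-connectivity", {
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 1L; m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_length(label_regions(m), 1)
  m[5, 5] <- 1L  # two steps away: separate region
  expect_length(label_regions(m), 2)
})

test_that("labeling agrees with a flood-fill oracle on random blob masks", {
  for (seed in c(5, 17, 29)) {
    s <- tiny_sample(dims = c(80, 80), count = 6, seed = seed,
                     area = c(8, 40))
    regs <- label_regions(s$mask)
    lab <- oracle_label8(s$mask)
    expect_equal(length(regs), max(lab))
    expect_equal(sort(vapply(regs, `[[`, 0L, "area")),
                 sort(unname(as.vector(table(lab[lab > 0])))))
    expect_equal(sum(vapply(regs, `[[`, 0L, "area")), sum(s$mask))
  }
})

test_that("regions order by area with deterministic tie-breaks", {
  m <- matrix(0L, 20, 20)
  m[2:5, 2:7] <- 1L    # 24 px
  m[10:17, 10:15] <- 1L  # 48 px
  regs <- label_regions(m)
  expect_equal(vapply(regs, `[[`, 0L, "area"), c(48L, 24L))
  expect_equal(vapply(regs, `[[`, 0L, "region_id"), 1:2)
})

test_that("centroid distances are Euclidean, symmetric, metric", {
  mk <- function(x, y) structure(list(region_id = 1, area = 1,
                                      centroid = c(x = x, y = y)),
                                 class = "pigment_region")
  D <- centroid_distances(list(mk(0, 0), mk(3, 4)))
  expect_equal(D[1, 2], 5)
  set.seed(171)
  pts <- lapply(1:6, function(i) mk(runif(1, 0, 50), runif(1, 0, 50)))
  D <- centroid_distances(pts)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 6))
  for (tri in 1:20) {
    ijk <- sample(6, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
  # brute-force pairwise check
  for (i in 1:6) for (j in 1:6)
    expect_equal(D[i, j], sqrt(sum((pts[[i]]$centroid -
                                      pts[[j]]$centroid)^2)))
})

test_that("reports assemble counts, sizes and distances, and round-trip", {
  empty <- pigment_report(matrix(0L, 8, 8), "healthy")
  expect_equal(empty$count, 0)
  expect_equal(dim(empty$distances), c(0L, 0L))
  m <- matrix(0L, 30, 30)
  m[2:5, 2:7] <- 1L; m[20:27, 20:25] <- 1L
  rep1 <- pigment_report(m, "visit-1")
  expect_equal(rep1$count, 2)
  expect_equal(vapply(rep1$regions, `[[`, 0L, "area"), c(48L, 24L))
  path <- tempfile(fileext = ".json")
  report_to_json(rep1, path)
  back <- report_from_json(path)
  expect_equal(back$count, rep1$count)
  expect_equal(back$distances, unname(rep1$distances),
               ignore_attr = TRUE)
  expect_equal(vapply(back$regions, `[[`, 0, "area"),
               vapply(rep1$regions, function(r) as.numeric(r$area), 0))
})

test_that("identical visits match perfectly; shifts are measured", {
  m <- matrix(0L, 40, 40)
  m[5:8, 5:10] <- 1L; m[25:30, 25:30] <- 1L
  a <- pigment_report(m, "a")
  cmp <- compare_visits(a, a)
  expect_equal(nrow(cmp$matched), 2L)
  expect_equal(cmp$matched$area_delta, c(0, 0))
  expect_equal(cmp$matched$displacement, c(0, 0))
  expect_length(cmp$appeared, 0)
  expect_length(cmp$disappeared, 0)
  # one blob moved 10 columns, same area
  m2 <- matrix(0L, 40, 40)
  m2[5:8, 15:20] <- 1L; m2[25:30, 25:30] <- 1L
  cmp2 <- compare_visits(a, pigment_report(m2, "b"), max_distance = 15)
  moved <- cmp2$matched[cmp2$matched$displacement > 0, ]
  expect_equal(moved$displacement, 10)
  expect_equal(moved$area_delta, 0)
  expect_error(compare_visits(a, pigment_report(matrix(0L, 10, 10), "c")),
               "different sizes")
})

test_that("greedy matching equals exhaustive assignment for small jitter", {
  set.seed(181)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    base <- cbind(runif(n, 10, 90), runif(n, 10, 90))
    while (min(dist(base)) < 20)
      base <- cbind(runif(n, 10, 90), runif(n, 10, 90))
    jitter <- base + matrix(runif(2 * n, -2, 2), n)
    mkrep <- function(xy) {
      regs <- lapply(seq_len(nrow(xy)), function(i)
        structure(list(region_id = i, area = 10L,
                       centroid = c(x = xy[i, 1], y = xy[i, 2]),
                       bounding_box = c(0L, 0L, 1L, 1L)),
                  class = "pigment_region"))
      structure(list(image_id = "x", image_dims = c(100L, 100L),
                     count = length(regs), regions = regs,
                     distances = centroid_distances(regs)),
                class = "pigment_report")
    }
    cmp <- compare_visits(mkrep(base), mkrep(jitter), max_distance = 8)
    oracle <- oracle_assignment(base, jitter, max_distance = 8)
    expect_equal(nrow(cmp$matched), length(oracle))
    got <- cmp$matched[order(cmp$matched$id_a), c("id_a", "id_b")]
    want <- do.call(rbind, oracle)[order(vapply(oracle, `[`, 0, 1)), ,
                                   drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(want))
  }
})

test_that("flipping a mask mirrors region centroids", {
  s <- tiny_sample(dims = c(64, 64), count = 4, seed = 191)
  regs <- label_regions(s$mask)
  flipped <- label_regions(s$mask[, ncol(s$mask):1])
  xs <- sort(vapply(regs, function(r) r$centroid[["x"]], 0))
  fx <- sort(vapply(flipped, function(r) r$centroid[["x"]], 0))
  expect_equal(fx, sort(ncol(s$mask) - 1 - xs))
})
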