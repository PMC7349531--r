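test_that("class frequencies use the per-class image denominator", {
  m <- matrix(0L, 10, 10); m[1, 1:10] <- 1L
  f <- class_frequencies(list(m))
  expect_equal(unname(f), c(0.9, 0.1))
  # pigment appears in only one of two masks: its denominator is that
  # image's pixels alone, background's spans both
  m2 <- matrix(0L, 10, 10)
  f2 <- class_frequencies(list(m, m2))
  expect_equal(f2[["pigment"]], 10 / 100)
  expect_equal(f2[["background"]], 190 / 200)
  expect_warning(class_frequencies(list(m2)), "pigment")
})

test_that("cohort frequencies match a brute-force pixel tally", {
  co <- generate_cohort(cohort_spec(n_patients = 2, images_per_patient = 3,
                                    image_dims = c(64, 64), seed = 23))
  masks <- lapply(co, `[[`, "mask")
  f <- class_frequencies(masks)
  pig_px <- 0; pig_den <- 0; bg_px <- 0; bg_den <- 0
  for (m in masks) {
    n1 <- 0L; n0 <- 0L
    for (v in as.vector(m)) if (v == 1L) n1 <- n1 + 1L else n0 <- n0 + 1L
    if (n1 > 0) { pig_px <- pig_px + n1; pig_den <- pig_den + length(m) }
    if (n0 > 0) { bg_px <- bg_px + n0; bg_den <- bg_den + length(m) }
  }
  expect_equal(f[["pigment"]], pig_px / pig_den)
  expect_equal(f[["background"]], bg_px / bg_den)
})

test_that("median-frequency weights satisfy weight * freq = median", {
  expect_equal(unname(median_frequency_weights(c(0.5, 0.5))), c(1, 1))
  w <- median_frequency_weights(c(a = 0.1, b = 0.9))
  expect_equal(unname(w), c(5, 5 / 9))
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    f <- runif(k, 0.01, 1)
    w <- median_frequency_weights(f)
    expect_equal(unname(w * f), rep(median(f), k))
    expect_true(all(w > 0))
  }
  expect_error(median_frequency_weights(c(0, 0.5)), "epsilon")
})

test_that("weighted pixel loss matches an explicit per-pixel loop", {
  set.seed(55)
  for (rep in 1:5) {
    d <- c(sample(3:9, 2), 2)
    p1 <- matrix(runif(d[1] * d[2]), d[1])
    prob <- array(c(1 - p1, p1), dim = d)
    mask <- matrix(rbinom(d[1] * d[2], 1, 0.4), d[1])
    w <- runif(2, 0.5, 8)
    expect_equal(weighted_pixel_loss(prob, mask, w),
                 oracle_weighted_loss(prob, mask, w))
  }
})

test_that("loss is zero for one-hot correct and ln 2 for uniform", {
  mask <- matrix(c(0L, 1L, 1L, 0L), 2)
  onehot <- array(0, c(2, 2, 2))
  onehot[cbind(c(row(mask)), c(col(mask)), c(mask) + 1L)] <- 1
  expect_equal(weighted_pixel_loss(onehot, mask, c(1, 1)), 0)
  expect_gt(weighted_pixel_loss(0.999 * onehot + 0.0005, mask, c(1, 1)), 0)
  uniform <- array(0.5, c(2, 2, 2))
  expect_equal(weighted_pixel_loss(uniform, mask, c(1, 1)), log(2))
})

test_that("patient folds partition the cohort and never share a patient", {
  co <- generate_cohort(cohort_spec(n_patients = 4, images_per_patient = 6,
                                    image_dims = c(64, 64), seed = 31))
  folds <- patient_kfold(co, k = 4)
  expect_equal(length(folds), 4L)
  test_keys <- unlist(lapply(folds, function(f)
    vapply(f$test, function(s) paste(s$patient_id, sum(s$mask),
                                     mean(s$image)), "")))
  all_keys <- vapply(co, function(s) paste(s$patient_id, sum(s$mask),
                                           mean(s$image)), "")
  expect_setequal(test_keys, all_keys)
  expect_equal(length(test_keys), length(all_keys))
  for (f in folds) {
    expect_equal(length(f$test), 6L)
    tr <- unique(vapply(f$train, function(s) s$patient_id, ""))
    te <- unique(vapply(f$test, function(s) s$patient_id, ""))
    expect_length(intersect(tr, te), 0)
  }
  expect_error(patient_kfold(co, k = 5), "exceeds")
})

test_that("training is deterministic given a seed", {
  ss <- lapply(1:3, function(i)
    tiny_sample(dims = c(32, 32), count = 2, seed = 60 + i, area = c(8, 20)))
  net <- build_network(rps_spec(input_rows = 32, input_cols = 32,
                                block_widths = c(2L, 3L, 4L, 5L)), seed = 9)
  cfg <- rps_train_config(learning_rate = 1e-3, epochs = 4, minibatch = 2,
                          seed = 33)
  a <- train_network(net, ss, cfg)
  b <- train_network(net, ss, cfg)
  expect_identical(a$history$loss, b$history$loss)
  expect_identical(a$net$params, b$net$params)
  # a different shuffle seed composes different minibatches
  c <- train_network(net, ss,
                     rps_train_config(learning_rate = 1e-3, epochs = 4,
                                      minibatch = 2, seed = 35))
  expect_false(identical(a$history$loss, c$history$loss))
})

test_that("a short run decreases the smoothed loss on a fixed batch", {
  s1 <- tiny_sample(dims = c(32, 32), count = 2, seed = 71, area = c(8, 20))
  s2 <- tiny_sample(dims = c(32, 32), count = 3, seed = 72, area = c(8, 20))
  net <- build_network(rps_spec(input_rows = 32, input_cols = 32,
                                block_widths = c(4L, 6L, 8L, 10L)), seed = 2)
  res <- train_network(net, list(s1, s2),
                       rps_train_config(learning_rate = 3e-3, epochs = 60,
                                        minibatch = 2, seed = 3))
  h <- res$history$loss
  expect_equal(length(h), 60L)  # epochs x ceil(N / minibatch)
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
  expect_true(all(is.finite(h)))
})

test_that("gradient clipping bounds the applied global norm", {
  g <- list(a = list(w = matrix(3, 2, 2)), b = list(w = matrix(4, 2, 2)))
  expect_equal(rpsnet:::.global_norm(g), 10)
  clipped <- rapply(g, function(x) x * 5 / 10, how = "replace")
  expect_equal(rpsnet:::.global_norm(clipped), 5)
})
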