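test_that("confusion counts follow the four pixel definitions", {
  t <- matrix(0L, 10, 10); t[1, 1:10] <- 1L
  expect_equal(unclass(confusion_counts(t, t))[c("FP", "FN")],
               list(FP = 0L, FN = 0L))
  none <- matrix(0L, 10, 10)
  cc <- confusion_counts(none, t)
  expect_equal(cc$FN, 10L); expect_equal(cc$TP, 0L)
  expect_equal(cc$TN, 90L)
  set.seed(91)
  for (rep in 1:10) {
    d <- sample(3:12, 2)
    pred <- matrix(rbinom(prod(d), 1, 0.3), d[1])
    tru <- matrix(rbinom(prod(d), 1, 0.2), d[1])
    expect_equal(unclass(confusion_counts(pred, tru))[1:4],
                 oracle_confusion(pred, tru))
    cc <- confusion_counts(pred, tru)
    expect_equal(cc$TP + cc$FN + cc$FP + cc$TN, prod(d))
  }
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "dimensions")
})

test_that("the five metrics follow their closed forms", {
  cc <- structure(list(TP = 8, FN = 2, FP = 2, TN = 88),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$Sen, 0.8)
  expect_equal(m$Spe, 88 / 90)
  expect_equal(m$P, 0.8)
  expect_equal(m$Acc, 0.96)
  expect_equal(m$F, 0.8)
  expect_length(m$degenerate, 0)
})

test_that("0/0 denominators yield 0 with a degenerate flag", {
  cc <- structure(list(TP = 0, FN = 0, FP = 0, TN = 50),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$Sen, 0)
  expect_equal(m$F, 0)
  expect_true(all(c("Sen", "P", "F") %in% m$degenerate))
  expect_equal(m$Acc, 1)
})

test_that("F equals the harmonic mean of precision and sensitivity", {
  set.seed(101)
  for (rep in 1:50) {
    cc <- structure(as.list(setNames(rpois(4, 20) + 1, c("TP", "FN", "FP",
                                                         "TN"))),
                    class = "confusion_counts")
    m <- compute_metrics(cc)
    expect_equal(m$F, 2 * m$P * m$Sen / (m$P + m$Sen))
    expect_true(all(unlist(m[c("Sen", "Spe", "P", "Acc", "F")]) >= 0 &
                      unlist(m[c("Sen", "Spe", "P", "Acc", "F")]) <= 1))
  }
})

test_that("ROC hits AUC 1 on separable scores and flags single-class truth", {
  truth <- matrix(rep(c(0L, 1L), each = 50), 10)
  prob <- matrix(ifelse(truth == 1L, 0.9, 0.1), 10)
  roc <- roc_and_auc(prob, truth)
  expect_equal(roc$auc, 1.0)
  expect_error(roc_and_auc(prob, matrix(0L, 10, 10)), "single class")
  expect_error(roc_and_auc(prob * 2, truth), "outside")
})

test_that("label-independent scores give AUC near one half", {
  set.seed(111)
  truth <- matrix(rbinom(20000, 1, 0.3), 100)
  prob <- matrix(runif(20000), 100)
  roc <- roc_and_auc(prob, truth, n_thresholds = 201L)
  expect_equal(roc$auc, 0.5, tolerance = 0.02)
})

test_that("own AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(121)
  truth <- matrix(rbinom(4000, 1, 0.2), 40)
  prob <- matrix(pmin(pmax(truth * 0.35 + runif(4000) * 0.65, 0), 1), 40)
  ours <- roc_and_auc(prob, truth, n_thresholds = 2001L)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(truth), as.vector(prob),
                                        quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 0.005)
})

test_that("AUC is invariant to strictly monotone probability transforms", {
  set.seed(131)
  truth <- matrix(rbinom(2500, 1, 0.25), 50)
  prob <- matrix(pmin(pmax(truth * 0.3 + runif(2500) * 0.7, 0), 1), 50)
  a1 <- roc_and_auc(prob, truth, n_thresholds = 501L)$auc
  a2 <- roc_and_auc(sqrt(prob), truth, n_thresholds = 501L)$auc
  expect_equal(a1, a2, tolerance = 0.01)
})

test_that("the EER point balances sensitivity and specificity", {
  set.seed(141)
  truth <- matrix(rbinom(5000, 1, 0.3), 50)
  prob <- matrix(pmin(pmax(truth * 0.4 + runif(5000) * 0.6, 0), 1), 50)
  roc <- roc_and_auc(prob, truth, n_thresholds = 501L)
  expect_lt(abs(roc$eer$sen - roc$eer$spe), 0.01)
})

test_that("upscaling is bilinear, range-preserving, and identity at size", {
  p <- matrix(runif(12 * 9), 12)
  expect_identical(upscale_prediction(p, c(12, 9)), p)
  const <- matrix(0.37, 10, 10)
  up <- upscale_prediction(const, c(33, 47))
  expect_equal(dim(up), c(33L, 47L))
  expect_equal(range(up), c(0.37, 0.37))
  big <- upscale_prediction(matrix(runif(400 * 300), 400), c(1440, 2160))
  expect_equal(dim(big), c(1440L, 2160L))
  expect_true(all(big >= 0 & big <= 1))
  # interpolation, not replication: intermediate values appear
  ramp <- upscale_prediction(matrix(c(0, 1, 0, 1), 2), c(8, 8))
  expect_gt(sum(ramp > 0.05 & ramp < 0.95), 0)
})

test_that("fold evaluation pools counts additively across images", {
  samples <- lapply(1:3, function(i)
    tiny_sample(dims = c(32, 32), count = 2, seed = 150 + i,
                area = c(8, 20)))
  net <- build_network(rps_spec(input_rows = 32, input_cols = 32,
                                block_widths = c(2L, 3L, 4L, 5L)), seed = 6)
  ev <- evaluate_fold(net, samples)
  sums <- colSums(ev$per_image[, c("TP", "FN", "FP", "TN")])
  expect_equal(unname(sums),
               unlist(ev$counts[c("TP", "FN", "FP", "TN")],
                      use.names = FALSE))
  expect_equal(sum(sums), 3 * 32 * 32)
  # micro-average: pooled metrics equal metrics of summed counts
  expect_equal(ev$metrics$Acc,
               (ev$counts$TP + ev$counts$TN) / sum(sums))
})

test_that("evaluation against native-resolution masks upscales first", {
  s <- tiny_sample(dims = c(32, 32), count = 2, seed = 161, area = c(8, 20))
  native <- matrix(0L, 64, 64)
  native[1:5, 1:5] <- 1L
  net <- build_network(rps_spec(input_rows = 32, input_cols = 32,
                                block_widths = c(2L, 3L, 4L, 5L)), seed = 6)
  ev <- evaluate_fold(net, list(s), native_masks = list(native))
  expect_equal(ev$counts$TP + ev$counts$FN + ev$counts$FP + ev$counts$TN,
               64 * 64)
})
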