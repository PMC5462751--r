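test_that("worked four-variant example reproduces by hand", {
  scores <- c(0.9, 0.8, 0.7, 0.1)
  labels <- c(1, 0, 1, 0)
  expect_equal(auprc(scores, labels), (1 + 2 / 3) / 2)
  prf <- prf_curve(scores, labels, thresholds = 0.75)
  expect_equal(prf$precision, 0.5)
  expect_equal(prf$recall, 0.5)
  expect_equal(prf$f, 0.5)
})

test_that("perfect separation and all-tie edge cases", {
  scores <- c(1, 1, 0, 0)
  labels <- c(1, 1, 0, 0)
  expect_equal(auprc(scores, labels), 1)
  expect_equal(auroc(scores, labels), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auprc(1:3, c(1, 1, 1)), "at least one")
  expect_error(auroc(1:3, c(0, 0, 0)), "at least one")
})

test_that("areas match brute-force oracles on random small instances", {
  set.seed(31)
  for (run in 1:50) {
    n <- sample(3:12, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)   # coarse scores force ties
    expect_equal(auprc(scores, labels), bf_average_precision(scores, labels))
    expect_equal(auroc(scores, labels), bf_auroc(scores, labels))
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  set.seed(32)
  labels <- sample(0:1, 300, replace = TRUE, prob = c(0.9, 0.1))
  labels[1:2] <- c(0, 1)
  scores <- rnorm(300) + labels
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))))
})

test_that("ranking metrics are invariant under monotone score transforms", {
  set.seed(33)
  labels <- sample(0:1, 60, replace = TRUE)
  labels[1:2] <- c(0, 1)
  scores <- runif(60)
  for (g in list(function(s) 2 * s + 1, exp, function(s) s^3)) {
    expect_equal(auprc(g(scores), labels), auprc(scores, labels))
    expect_equal(auroc(g(scores), labels), auroc(scores, labels))
  }
})

test_that("AUPRC separates rankings that AUROC cannot distinguish", {
  # 3 positives among 100 variants; both rankings have the same positive
  # rank sum (103) hence identical AUROC, but one is top-loaded and the
  # other buried: under imbalance the PR view tells them apart
  top_loaded <- rep(0, 100); top_loaded[c(1, 2, 100)] <- 1
  interleaved <- rep(0, 100); interleaved[c(33, 34, 36)] <- 1
  scores <- (100:1) / 100
  expect_equal(auroc(scores, top_loaded), auroc(scores, interleaved))
  expect_gt(auprc(scores, top_loaded), auprc(scores, interleaved))
})

test_that("precision/recall/F behave across the threshold sweep", {
  set.seed(34)
  labels <- sample(0:1, 80, replace = TRUE, prob = c(0.8, 0.2))
  labels[1:2] <- c(0, 1)
  scores <- runif(80)
  prf <- prf_curve(scores, labels, thresholds = seq(0, 1, 0.1))
  # t = 0 predicts everything positive
  expect_equal(prf$recall[1], 1)
  expect_equal(prf$precision[1], mean(labels))
  # F is a harmonic mean: between min and max of precision and recall
  ok <- !prf$degenerate & prf$recall > 0
  expect_true(all(prf$f[ok] >= pmin(prf$precision, prf$recall)[ok] - 1e-12))
  expect_true(all(prf$f[ok] <= pmax(prf$precision, prf$recall)[ok] + 1e-12))
  # above the maximum score nothing is predicted: flagged, precision 1
  high <- prf_curve(c(0.2, 0.4), c(0, 1), thresholds = 0.9)
  expect_true(high$degenerate)
  expect_equal(high$precision, 1)
  expect_equal(high$recall, 0)
  expect_error(prf_curve(scores, labels, thresholds = 1.5), "\\[0, 1\\]")
})

test_that("sensitivity vs quantile matches the sort-count oracle", {
  # 1000 variants, 10 positives, exactly one positive at the very top:
  # sensitivity at quantile 1e-3 is 0.1
  scores <- seq(1, 0.001, length.out = 1000)
  labels <- rep(0, 1000)
  labels[c(1, sample(301:1000, 9))] <- 1
  sq <- sensitivity_quantile(scores, labels, quantiles = c(1e-3, 1))
  expect_equal(sq$sensitivity[1], 0.1)
  expect_equal(sq$sensitivity[2], 1)

  set.seed(35)
  for (run in 1:10) {
    n <- sample(20:200, 1)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
    labels[1:2] <- c(0, 1)
    scores <- runif(n)
    qs <- sort(runif(5))
    sq <- sensitivity_quantile(scores, labels, quantiles = qs)
    expect_equal(sq$sensitivity,
                 vapply(qs, function(q) bf_sensitivity(scores, labels, q), 0))
    expect_true(all(diff(sq$sensitivity) >= 0))   # non-decreasing in q
  }
  expect_error(sensitivity_quantile(scores, labels, quantiles = 0), "\\(0, 1\\]")
})

test_that("ranking_curves bundles consistent derived curves", {
  set.seed(36)
  labels <- sample(0:1, 100, replace = TRUE, prob = c(0.85, 0.15))
  labels[1:2] <- c(0, 1)
  scores <- runif(100) + 0.5 * labels
  rc <- ranking_curves(scores, labels)
  expect_s3_class(rc, "ranking_curves")
  expect_equal(rc$auprc, auprc(scores, labels))
  expect_equal(rc$auroc, auroc(scores, labels))
  expect_true(all(diff(rc$pr$recall) >= 0))        # recall sweep monotone
  expect_true(all(rc$roc$tpr >= 0 & rc$roc$tpr <= 1))
  expect_equal(rc$sensitivity$sensitivity[nrow(rc$sensitivity)], 1)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(rc, which = "pr"))
  expect_invisible(plot(rc, which = "sensitivity"))
})
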