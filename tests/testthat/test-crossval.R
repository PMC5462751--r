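test_that("genomic order is natural: chr2 before chr10, X/Y/MT last", {
  chrom <- c("chr10", "chr2", "chrX", "chr1", "chrMT", "chrY")
  pos <- c(5, 5, 5, 5, 5, 5)
  expect_equal(chrom[genomic_order(chrom, pos)],
               c("chr1", "chr2", "chr10", "chrX", "chrY", "chrMT"))
  expect_equal(genomic_order(c("chr1", "chr1"), c(200, 100)), c(2L, 1L))
})

test_that("greedy band assignment balances per-fold positive totals", {
  # bands with positive counts 3,2,2,1,1 over 2 folds -> totals {5, 4}
  band <- rep(c("b1", "b2", "b3", "b4", "b5"), c(3, 2, 2, 1, 1))
  folds <- cytoband_folds(band, rep(1, 9), n_folds = 2, seed = 1)
  totals <- table(folds)
  expect_setequal(as.integer(totals), c(5, 4))
  # atomicity: every band in exactly one fold
  expect_true(all(vapply(split(folds, band), function(f)
    length(unique(f)) == 1L, TRUE)))
})

test_that("bands are atomic and negatives inherit their band's fold", {
  bench <- sim_with_folds(n_pos = 25, n_neg = 400, n_folds = 10, seed = 2)
  folds <- bench$folds
  band <- bench$sim$band
  expect_true(all(vapply(split(folds, band), function(f)
    length(unique(f)) == 1L, TRUE)))
  expect_equal(attr(folds, "n_folds"), 10L)

  # one positive per band: per-fold positive counts within +/- 1
  band2 <- c(paste0("pb", 1:20), sample(paste0("nb", 1:10), 300, TRUE))
  lab2 <- rep(c(1, 0), c(20, 300))
  f2 <- cytoband_folds(band2, lab2, n_folds = 10, seed = 3)
  pos_per_fold <- table(factor(f2[lab2 == 1], levels = 1:10))
  expect_lte(diff(range(pos_per_fold)), 1)

  expect_error(cytoband_folds(c("b1", NA), c(1, 0), n_folds = 2),
               "band")
  expect_warning(cytoband_folds(rep("b1", 5), c(1, 1, 0, 0, 0),
                                n_folds = 3, seed = 1),
                 "lack")
})

test_that("overlapping windows around positives merge into one fold", {
  # positives 50 kb apart with +/- 100 kb windows: a single merged fold
  res <- matched_negative_folds(
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    pos = c(100000, 150000, 200000, 260000),
    labels = c(1, 1, 0, 0),
    window = 1e5)
  expect_equal(res$selected, 1:3)      # 260 kb is beyond 250 kb
  expect_equal(res$fold, c(1L, 1L, 1L))

  # merged span agrees with an independent interval-union implementation
  p <- sort(sample.int(1e6, 20))
  ir <- IRanges::reduce(IRanges::IRanges(start = pmax(1, p - 5e4),
                                         end = p + 5e4))
  res2 <- suppressWarnings(
    matched_negative_folds(rep("chr1", 20), p, rep(1, 20), window = 5e4))
  expect_equal(length(unique(res2$fold)), length(ir))
})

test_that("window selection follows strict distance arithmetic", {
  res <- suppressWarnings(matched_negative_folds(
    chrom = rep("chr2", 5),
    pos = c(500000, 401000, 599000, 601000, 700000),
    labels = c(1, 0, 0, 0, 0),
    window = 1e5))
  expect_equal(res$selected, 1:3)   # 601 kb and 700 kb are out of range
  # no selected negative farther than the window from every positive
  expect_true(all(abs(c(401000, 599000) - 500000) <= 1e5))
})

test_that("TAD folds keep only negatives sharing a TAD with a positive", {
  tads <- data.frame(chrom = "chr1",
                     start = c(0, 1000, 2000),
                     end = c(1000, 2000, 3000),
                     name = c("t1", "t2", "t3"))
  chrom <- rep("chr1", 7)
  pos <- c(100, 1500, 200, 900, 1100, 2500, 2900)
  labels <- c(1, 1, 0, 0, 0, 0, 0)
  res <- matched_negative_folds(chrom, pos, labels, tads = tads)
  expect_equal(res$selected, 1:5)           # TAD t3 holds no positive
  expect_equal(length(unique(res$fold)), 2)
  expect_equal(res$fold[1], res$fold[3])    # same TAD, same fold
  expect_equal(res$fold[1], res$fold[4])
  expect_equal(res$fold[2], res$fold[5])

  expect_warning(
    matched_negative_folds("chr9", 5000, 1, tads = tads),
    "outside every TAD")
})

test_that("progressive subsampling keeps every s-th sorted negative", {
  pos <- sort(sample.int(1e7, 100))
  sel <- progressive_subsample(rep("chr3", 100), pos, 10)
  expect_equal(sel, seq(1, 91, by = 10))
  expect_equal(progressive_subsample(rep("chr3", 100), pos, 100), 1:100)
  expect_error(progressive_subsample(rep("chr3", 100), pos, 101),
               "exceeds")

  # genomic coverage preserved: selection spans first and last decile
  for (target in c(10, 25, 50)) {
    sel <- progressive_subsample(rep("chr3", 100), pos, target)
    r <- range(pos[sel])
    span <- range(pos)
    expect_lte(r[1], span[1] + 0.1 * diff(span))
    expect_gte(r[2], span[2] - 0.1 * diff(span))
  }
})

test_that("subsampling targets scale the imbalance ratio as 1:1 .. 1:1000", {
  n_pos <- 40
  n_neg <- 40000
  pos <- sort(sample.int(2e8, n_neg))
  for (ratio in c(1, 10, 100, 1000)) {
    sel <- progressive_subsample(rep("chr1", n_neg), pos, n_pos * ratio)
    expect_equal(length(sel) / n_pos, ratio)
  }
})

test_that("out-of-fold scores never come from a model that saw the variant", {
  bench <- sim_with_folds(n_pos = 16, n_neg = 160, n_folds = 2, seed = 14)
  cv <- suppressWarnings(
    smurf_cv(bench$x, bench$y, bench$folds, n = 3, seed = 7))
  expect_true(cv_audit(cv))
  for (p in cv$provenance) {
    expect_length(intersect(p$train_rows, p$test_rows), 0)
  }
  expect_false(anyNA(cv$scores))
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))

  # determinism: identical seed, identical pooled scores
  cv2 <- suppressWarnings(
    smurf_cv(bench$x, bench$y, bench$folds, n = 3, seed = 7))
  expect_identical(cv$scores, cv2$scores)
})

test_that("a planted leak is caught by the provenance audit", {
  bench <- sim_with_folds(n_pos = 16, n_neg = 160, n_folds = 2, seed = 15)
  cv <- suppressWarnings(
    smurf_cv(bench$x, bench$y, bench$folds, n = 2, seed = 7))
  leaked <- cv
  held_out_positive <- leaked$provenance[[1]]$test_rows[
    bench$y[leaked$provenance[[1]]$test_rows] == 1][1]
  leaked$provenance[[1]]$train_rows <-
    c(leaked$provenance[[1]]$train_rows, held_out_positive)
  expect_error(cv_audit(leaked), "audit failed")
})

test_that("cv refuses folds without training positives", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1, 0), c(4, 16))
  folds <- rep(2, 20); folds[y == 1] <- 1   # all positives held out in fold 1
  expect_error(suppressWarnings(smurf_cv(x, y, folds, n = 2, seed = 1)),
               "zero training positives")
})
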