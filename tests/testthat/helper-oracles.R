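# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops, exhaustive scans, and
# literal rank walks.

# exhaustive k-NN: full distance scan, ties broken by ascending index
bf_knn <- function(x, i, k) {
  d <- apply(x, 1, function(row) sqrt(sum((row - x[i, ])^2)))
  ord <- order(d, seq_len(nrow(x)))
  ord <- ord[ord != i]
  ord[seq_len(min(k, nrow(x) - 1L))]
}

# literal rank-walk average precision (descending scores, input-order ties)
bf_average_precision <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  hits <- 0; total <- 0
  for (r in seq_along(lab)) {
    if (lab[r] == 1) {
      hits <- hits + 1
      total <- total + hits / r
    }
  }
  total / sum(labels == 1)
}

# exhaustive Mann-Whitney pair count with half tie credit
bf_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  wins <- 0
  for (a in sp) for (b in sn) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(sp) * length(sn))
}

# explicit sort-and-count sensitivity at a quantile
bf_sensitivity <- function(scores, labels, q) {
  ord <- order(-scores, seq_along(scores))
  top <- ord[seq_len(min(ceiling(q * length(scores)), length(scores)))]
  sum(labels[top] == 1) / sum(labels == 1)
}

# Euclidean distance from point p to the segment [a, b]
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
  sqrt(sum((p - (a + t * ab))^2))
}

random_positive_set <- function(n, d) {
  matrix(rnorm(n * d), n, d)
}

# small simulated benchmark plus cytoband folds, shared by several tests
sim_with_folds <- function(n_pos = 30, n_neg = 300, n_folds = 3, seed = 1,
                           ...) {
  sim <- simulate_variants(n_pos = n_pos, n_neg = n_neg, seed = seed, ...)
  feats <- feature_columns(sim)
  folds <- suppressWarnings(
    cytoband_folds(sim$band, sim$label, n_folds = n_folds, seed = seed))
  list(sim = sim, x = as.matrix(sim[feats]), y = sim$label, folds = folds)
}

# pooled out-of-fold scores for a plain single forest (imbalance-unaware
# baseline), using ranger directly so the comparison is external to smurf
baseline_cv_scores <- function(x, y, folds, ntree = 10, seed = 1) {
  scores <- rep(NA_real_, nrow(x))
  for (fid in sort(unique(folds))) {
    tr <- folds != fid
    fit <- ranger::ranger(x = x[tr, , drop = FALSE],
                          y = factor(y[tr], levels = c(0, 1)),
                          num.trees = ntree, probability = TRUE,
                          min.node.size = 1, seed = seed + fid,
                          num.threads = 1)
    scores[!tr] <- predict(fit, data = x[!tr, , drop = FALSE],
                           num.threads = 1)$predictions[, "1"]
  }
  scores
}

# seeded permutation that leaves the caller's RNG stream untouched
with_seed_shuffle <- function(v, seed) {
  state <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(seed)
  sample(v)
}
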