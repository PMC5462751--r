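# Ranking metrics for heavily imbalanced scoring problems.
#
# Under extreme class imbalance the precision-recall view is far more
# informative than the ROC view: a scorer can reach a near-perfect AUROC
# while burying most positives below thousands of negatives. AUPRC is
# therefore the primary metric; AUROC, threshold curves and
# sensitivity-vs-quantile curves complete the picture.

check_scores_labels <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  labels
}

check_two_classes <- function(labels) {
  if (all(labels == 1L) || all(labels == 0L)) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
}

# stable descending rank order: ties broken by input position
rank_order <- function(scores) order(-scores, seq_along(scores))

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision: variants are ranked by descending
#' score (ties broken by input order) and the precision at the rank of each
#' positive is averaged. Linear interpolation of the PR curve is known to
#' overestimate the area, so the average-precision estimator is used and
#' documented here.
#'
#' @param scores numeric scores, larger = more deleterious.
#' @param labels binary labels (1 = positive).
#' @return average precision in \eqn{(0, 1]}.
#' @examples
#' auprc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)) # (1 + 2/3) / 2
#' @export
auprc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  check_two_classes(labels)
  ranked <- labels[rank_order(scores)]
  hits <- which(ranked == 1L)
  mean(seq_along(hits) / hits)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, with ties credited 1/2. This is
#' exact (no trapezoid approximation is needed).
#'
#' @inheritParams auprc
#' @return AUROC in \eqn{[0, 1]}.
#' @export
auroc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  check_two_classes(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores)                       # midranks handle tie credit
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision, recall and F-score as a function of the score threshold
#'
#' At each threshold \code{t} every variant with \code{score >= t} is
#' predicted deleterious. When no variant is predicted positive the
#' precision is undefined; it is reported as 1.0 and flagged in the
#' \code{degenerate} column.
#'
#' @inheritParams auprc
#' @param thresholds numeric thresholds in \eqn{[0, 1]}.
#' @return data frame with columns \code{threshold}, \code{precision},
#'   \code{recall}, \code{f} (the F1 score) and \code{degenerate}.
#' @export
prf_curve <- function(scores, labels, thresholds = seq(0, 1, by = 0.05)) {
  labels <- check_scores_labels(scores, labels)
  if (anyNA(thresholds) || any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  out <- lapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    degenerate <- (tp + fp) == 0L
    precision <- if (degenerate) 1 else tp / (tp + fp)
    recall <- tp / n_pos
    f <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(threshold = t, precision = precision, recall = recall,
               f = f, degenerate = degenerate)
  })
  do.call(rbind, out)
}

#' Sensitivity among the top-ranked quantile of variants
#'
#' For each quantile \code{q} in \eqn{(0, 1]}, the fraction of all
#' positives found among the top \code{ceiling(q * T)} ranked variants
#' (\code{T} = total variants). A sensitivity of 0.1 at quantile 1e-3 means
#' one tenth of the positives lie in the top thousandth of the ranking.
#'
#' @inheritParams auprc
#' @param quantiles numeric quantiles in \eqn{(0, 1]}.
#' @return data frame with columns \code{quantile} and \code{sensitivity}.
#' @export
sensitivity_quantile <- function(scores, labels,
                                 quantiles = 10^seq(-4, 0, by = 0.25)) {
  labels <- check_scores_labels(scores, labels)
  check_two_classes(labels)
  if (any(quantiles <= 0 | quantiles > 1)) {
    stop("quantiles must lie in (0, 1]", call. = FALSE)
  }
  ranked <- labels[rank_order(scores)]
  cum_pos <- cumsum(ranked)
  n_pos <- cum_pos[length(cum_pos)]
  top <- pmin(ceiling(quantiles * length(ranked)), length(ranked))
  data.frame(quantile = quantiles, sensitivity = cum_pos[top] / n_pos)
}

#' Ranking curves for a scored variant set
#'
#' Bundles the score/label vectors with their derived precision-recall
#' curve, ROC curve, threshold curves and sensitivity-vs-quantile curve,
#' plus the two areas.
#'
#' @inheritParams auprc
#' @param thresholds thresholds for the precision/recall/F sweep.
#' @param quantiles quantiles for the sensitivity sweep.
#' @return an object of class \code{"ranking_curves"} with elements
#'   \code{auprc}, \code{auroc}, \code{pr}, \code{roc}, \code{prf},
#'   \code{sensitivity}.
#' @export
ranking_curves <- function(scores, labels,
                           thresholds = seq(0, 1, by = 0.05),
                           quantiles = 10^seq(-4, 0, by = 0.25)) {
  labels <- check_scores_labels(scores, labels)
  check_two_classes(labels)
  ranked <- labels[rank_order(scores)]
  n_pos <- sum(ranked == 1L)
  n_neg <- sum(ranked == 0L)
  tp <- cumsum(ranked)
  fp <- seq_along(ranked) - tp
  pr <- data.frame(recall = tp / n_pos,
                   precision = tp / seq_along(ranked))
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(
    scores = scores, labels = labels,
    auprc = auprc(scores, labels), auroc = auroc(scores, labels),
    pr = pr, roc = roc,
    prf = prf_curve(scores, labels, thresholds),
    sensitivity = sensitivity_quantile(scores, labels, quantiles)
  ), class = "ranking_curves")
}

#' @export
print.ranking_curves <- function(x, ...) {
  cat(sprintf("Ranking of %d variants (%d positive, imbalance 1:%.0f)\n",
              length(x$labels), sum(x$labels == 1L),
              imbalance_ratio(sum(x$labels == 1L), sum(x$labels == 0L))))
  cat(sprintf("  AUPRC (average precision): %.4f\n", x$auprc))
  cat(sprintf("  AUROC (Mann-Whitney):      %.4f\n", x$auroc))
  invisible(x)
}

#' Plot ranking curves
#'
#' @param x a \code{"ranking_curves"} object.
#' @param which one of \code{"pr"}, \code{"roc"}, \code{"sensitivity"},
#'   \code{"f"}.
#' @param ... passed to \code{plot}.
#' @export
plot.ranking_curves <- function(x, which = c("pr", "roc", "sensitivity", "f"),
                                ...) {
  which <- match.arg(which)
  switch(which,
    pr = graphics::plot(
      x$pr$recall, x$pr$precision, type = "l", ylim = c(0, 1),
      xlab = "Recall", ylab = "Precision",
      main = sprintf("Precision-recall (AUPRC = %.3f)", x$auprc), ...),
    roc = {
      graphics::plot(
        x$roc$fpr, x$roc$tpr, type = "l",
        xlab = "False positive rate", ylab = "True positive rate",
        main = sprintf("ROC (AUROC = %.3f)", x$auroc), ...)
      graphics::abline(0, 1, lty = 2)
    },
    sensitivity = graphics::plot(
      log10(x$sensitivity$quantile), x$sensitivity$sensitivity,
      type = "b", ylim = c(0, 1),
      xlab = "log10 quantile of top-ranked variants",
      ylab = "Sensitivity", main = "Sensitivity vs top-ranked quantile",
      ...),
    f = graphics::plot(
      x$prf$threshold, x$prf$f, type = "b", ylim = c(0, 1),
      xlab = "Score threshold", ylab = "F-score",
      main = "F-score vs threshold", ...)
  )
  invisible(x)
}
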