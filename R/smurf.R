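#' Partition negative examples into n disjoint subsets
#'
#' Shuffles the negative row indices and splits them into \code{n}
#' near-equal parts (sizes differ by at most one) that are pairwise
#' disjoint and jointly cover all negatives.
#'
#' @param negatives integer vector of negative row indices.
#' @param n number of partitions.
#' @param seed optional integer seed.
#' @return list of \code{n} integer vectors.
#' @export
partition_negatives <- function(negatives, n, seed = NULL) {
  n <- check_count(n, "n")
  nn <- length(negatives)
  if (nn < n) {
    stop(sprintf("cannot split %d negatives into %d partitions", nn, n),
         call. = FALSE)
  }
  with_seed(seed, {
    shuffled <- negatives[sample.int(nn)]
    grp <- rep(seq_len(n), length.out = nn)
    # rep() cycles 1..n so sizes differ by <= 1
    unname(split(shuffled, grp))
  })
}

#' Undersample a negative partition
#'
#' Draws \code{n_ex} indices uniformly without replacement. A partition
#' smaller than \code{n_ex} is returned whole, with a warning: sampling
#' with replacement would bias the trees towards duplicated negatives.
#'
#' @param partition integer vector of negative row indices.
#' @param n_ex number of negatives to draw.
#' @param seed optional integer seed.
#' @return integer vector of \code{min(n_ex, length(partition))} indices.
#' @export
undersample_negatives <- function(partition, n_ex, seed = NULL) {
  n_ex <- check_count(n_ex, "n_ex")
  if (length(partition) == 0L) stop("empty negative partition", call. = FALSE)
  if (length(partition) <= n_ex) {
    if (length(partition) < n_ex) {
      warning(sprintf(
        "partition of size %d smaller than requested n_ex = %d; using all",
        length(partition), n_ex), call. = FALSE)
    }
    return(partition)
  }
  with_seed(seed, partition[sample.int(length(partition), n_ex)])
}

#' Fit a hyper-ensemble of SMOTE-undersampled random forests
#'
#' Trains the imbalance-aware hyper-ensemble: the negatives are split into
#' \code{n} disjoint partitions; for each partition the positives are
#' augmented with \code{f} SMOTE synthetics per positive, the partition is
#' undersampled to \eqn{n_{ex} = m (f + 1) |P|} negatives, and a
#' probability random forest is fitted on the union. With \code{m = 1}
#' every training set is exactly balanced; larger \code{m} exploits more
#' negatives per learner. Scores for new variants are the mean
#' probability-of-deleteriousness across the \code{n} forests (see
#' \code{\link{predict.smurf}}).
#'
#' SMOTE is re-run independently for every partition, so each forest sees
#' different synthetics — an extra source of ensemble diversity. A master
#' \code{seed} deterministically derives per-partition sub-seeds (SMOTE,
#' undersampling, tree growth), so results do not depend on the order in
#' which partitions are processed.
#'
#' @param x feature matrix (rows = variants), or a formula.
#' @param y binary labels: 1 = deleterious, 0 = non-deleterious.
#' @param n number of negative partitions / base forests.
#' @param f SMOTE oversampling factor (synthetics per positive).
#' @param m undersampling factor: each forest trains on \code{m} times as
#'   many negatives as positives-plus-synthetics.
#' @param k SMOTE neighbour count.
#' @param ntree trees per base forest.
#' @param mtry features tried per split; default \code{ceiling(sqrt(d))}.
#' @param seed master seed governing all randomness of the fit.
#' @param data data frame holding the variables of the formula method.
#' @param ... passed between methods.
#' @return an object of class \code{"smurf"}: the \code{n} fitted forests,
#'   the configuration, and per-partition bookkeeping (positive, synthetic
#'   and negative training counts, and which negative rows each forest
#'   saw).
#' @seealso \code{\link{predict.smurf}}, \code{\link{smurf_cv}},
#'   \code{\link{smote}}
#' @examples
#' sim <- simulate_variants(n_pos = 20, n_neg = 200, seed = 1)
#' fit <- smurf(label ~ ., data = sim[, -(1:4)], n = 3, seed = 1)
#' summary(fit)
#' @export
smurf <- function(x, ...) UseMethod("smurf")

#' @rdname smurf
#' @param formula a formula such as \code{label ~ .}; all right-hand-side
#'   variables must be numeric features.
#' @export
smurf.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as_feature_matrix(mf[, -1L, drop = FALSE])
  out <- smurf.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname smurf
#' @export
smurf.default <- function(x, y, n = 10L, f = 2L, m = 3L, k = 5L,
                          ntree = 10L, mtry = NULL, seed = NULL, ...) {
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)", call. = FALSE)
  n <- check_count(n, "n"); f <- check_count(f, "f")
  m <- check_count(m, "m"); k <- check_count(k, "k")
  ntree <- check_count(ntree, "ntree")
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(x)))

  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("need at least one positive and one negative example",
         call. = FALSE)
  }

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  sub <- derive_seeds(seed, 1L + 3L * n)
  parts <- partition_negatives(neg, n, seed = sub[1L])
  n_ex <- m * (f + 1L) * length(pos)

  models <- vector("list", n)
  bookkeeping <- vector("list", n)
  for (i in seq_len(n)) {
    s_smote <- sub[1L + i]
    s_under <- sub[1L + n + i]
    s_tree <- sub[1L + 2L * n + i]
    syn <- smote(x[pos, , drop = FALSE], f = f, k = k, seed = s_smote)
    sel <- undersample_negatives(parts[[i]], n_ex, seed = s_under)
    xt <- rbind(x[pos, , drop = FALSE], syn, x[sel, , drop = FALSE])
    yt <- factor(rep(c(1L, 0L), c(length(pos) + nrow(syn), length(sel))),
                 levels = c(0L, 1L))
    # fully grown trees (min.node.size = 1), the random-forest convention;
    # the forest's probability is then the tree-vote fraction
    models[[i]] <- ranger::ranger(
      x = xt, y = yt, num.trees = ntree, mtry = min(mtry, ncol(x)),
      probability = TRUE, min.node.size = 1L, seed = s_tree,
      num.threads = 1L)
    bookkeeping[[i]] <- list(
      n_pos = length(pos), n_syn = nrow(syn), n_neg = length(sel),
      partition = parts[[i]], negatives_used = sel)
  }

  structure(list(
    models = models,
    n = n, f = f, m = m, k = k, ntree = ntree, mtry = mtry,
    seed = seed, n_ex = n_ex,
    feature_names = colnames(x),
    n_pos = length(pos), n_neg = length(neg),
    partitions = bookkeeping,
    call = match.call()
  ), class = "smurf")
}

#' Score variants with a fitted hyper-ensemble
#'
#' The score of a variant is the arithmetic mean of the
#' probability-of-deleteriousness estimated by each of the \code{n} base
#' forests, and therefore always lies in \eqn{[0, 1]}.
#'
#' @param object a fitted \code{"smurf"} model.
#' @param newdata feature matrix or data frame with the training feature
#'   columns.
#' @param per_model if \code{TRUE}, return the \code{nrow(newdata) x n}
#'   matrix of per-forest probabilities instead of their mean.
#' @param ... ignored.
#' @return numeric vector of scores in \eqn{[0, 1]} (or the per-forest
#'   probability matrix).
#' @export
predict.smurf <- function(object, newdata, per_model = FALSE, ...) {
  newdata <- as_feature_matrix(
    if (is.data.frame(newdata))
      newdata[, object$feature_names, drop = FALSE]
    else newdata)
  if (ncol(newdata) != length(object$feature_names)) {
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), length(object$feature_names)),
         call. = FALSE)
  }
  colnames(newdata) <- object$feature_names
  probs <- vapply(object$models, function(mod) {
    stats::predict(mod, data = newdata,
                   num.threads = 1L)$predictions[, "1"]
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) probs <- matrix(probs, nrow = 1L)
  if (per_model) return(probs)
  rowMeans(probs)
}

#' @export
print.smurf <- function(x, ...) {
  cat("Hyper-ensemble of SMOTE-undersampled random forests\n")
  cat(sprintf("  %d base forests (%d trees each, mtry = %d)\n",
              x$n, x$ntree, x$mtry))
  cat(sprintf("  oversampling f = %d, undersampling m = %d, k = %d\n",
              x$f, x$m, x$k))
  cat(sprintf("  trained on %d positives, %d negatives (imbalance 1:%.0f)\n",
              x$n_pos, x$n_neg, imbalance_ratio(x$n_pos, x$n_neg)))
  invisible(x)
}

#' @export
summary.smurf <- function(object, ...) {
  tab <- do.call(rbind, lapply(seq_along(object$partitions), function(i) {
    b <- object$partitions[[i]]
    data.frame(partition = i, n_pos = b$n_pos, n_syn = b$n_syn,
               n_neg = b$n_neg,
               training_rows = b$n_pos + b$n_syn + b$n_neg)
  }))
  out <- list(model = object, partitions = tab)
  class(out) <- "summary.smurf"
  out
}

#' @export
print.summary.smurf <- function(x, ...) {
  print(x$model)
  cat("\nPer-partition training-set cardinalities (|P|, |P_S|, |N'|):\n")
  print(x$partitions, row.names = FALSE)
  invisible(x)
}

#' Imbalance ratio of a labelled set
#'
#' Negatives per positive; a data set with 406 positives and 14,755,199
#' negatives has an imbalance ratio of about 36,000 (i.e. 1:36,000).
#'
#' @param n_pos,n_neg class counts.
#' @return \code{n_neg / n_pos}.
#' @export
imbalance_ratio <- function(n_pos, n_neg) {
  if (n_pos <= 0 || n_neg < 0) stop("invalid class counts", call. = FALSE)
  n_neg / n_pos
}

#' Save / load a fitted hyper-ensemble
#'
#' Serialises the full model object (configuration plus fitted forests) to
#' a single archive file. The round trip is exact: scores computed from the
#' reloaded model are identical to those of the original.
#'
#' @param object a \code{"smurf"} model.
#' @param path file path of the model archive.
#' @return \code{smurf_load} returns the restored \code{"smurf"} object.
#' @export
smurf_save <- function(object, path) {
  stopifnot(inherits(object, "smurf"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname smurf_save
#' @export
smurf_load <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "smurf")) {
    stop("file does not contain a smurf model", call. = FALSE)
  }
  object
}
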