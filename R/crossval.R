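# Genomics-aware cross-validation.
#
# Variants that are genomically close share regulatory context, so random
# row-wise CV leaks location-linked signal between training and test sets.
# Folds are therefore built from atomic genomic units: cytogenetic bands,
# merged windows around positives, or TADs. No unit ever straddles folds.

chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.numeric(ch))
  r[ch %in% c("X", "x")] <- 23
  r[ch %in% c("Y", "y")] <- 24
  r[ch %in% c("MT", "M", "mt")] <- 25
  # anything non-standard sorts after, alphabetically
  other <- is.na(r)
  if (any(other)) r[other] <- 25 + as.numeric(factor(ch[other]))
  r
}

#' Order variants by genomic position
#'
#' Natural chromosome order (1..22, X, Y, MT, then others), position
#' ascending within chromosome.
#'
#' @param chrom chromosome names (with or without a "chr" prefix).
#' @param pos 1-based positions.
#' @return integer permutation, as from \code{order}.
#' @export
genomic_order <- function(chrom, pos) {
  order(chrom_rank(chrom), pos)
}

#' Cytogenetic-band-aware cross-validation folds
#'
#' Every band is atomic: all variants of a band share a fold. Bands holding
#' at least one positive are assigned greedily — descending positive count,
#' each to the fold currently lightest in positives — so per-fold positive
#' totals are balanced; positive-free bands are assigned uniformly at
#' random, and negatives inherit their band's fold.
#'
#' @param band cytogenetic band identifier per variant.
#' @param labels binary labels per variant.
#' @param n_folds number of folds (default 10).
#' @param seed optional seed for the placement of positive-free bands.
#' @return integer fold id (1..\code{n_folds}) per variant, with
#'   \code{n_folds} as an attribute.
#' @export
cytoband_folds <- function(band, labels, n_folds = 10L, seed = NULL) {
  labels <- as_binary_labels(labels)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  band <- as.character(band)
  if (anyNA(band) || any(band == "")) {
    stop("every variant needs a cytogenetic band", call. = FALSE)
  }
  pos_per_band <- table(band[labels == 1L])
  pos_bands <- names(pos_per_band)
  if (length(pos_bands) < n_folds) {
    warning(sprintf(
      "only %d bands contain positives; some of the %d folds will lack them",
      length(pos_bands), n_folds), call. = FALSE)
  }

  band_fold <- integer(0)
  # greedy longest-first bin packing of positive-bearing bands
  ord <- order(-as.integer(pos_per_band), pos_bands)
  load <- integer(n_folds)
  for (b in ord) {
    target <- which.min(load)          # ties -> lowest fold id
    band_fold[pos_bands[b]] <- target
    load[target] <- load[target] + as.integer(pos_per_band[b])
  }
  rest <- setdiff(unique(band), pos_bands)
  if (length(rest) > 0L) {
    band_fold[rest] <- with_seed(seed,
      sample.int(n_folds, length(rest), replace = TRUE))
  }
  structure(unname(band_fold[band]), n_folds = n_folds)
}

merge_intervals <- function(start, end) {
  # sort-and-sweep union of closed intervals
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Matched-negative selection with topologically-aware folds
#'
#' Keeps only the negatives that are genomically close to some positive and
#' builds one CV fold per contiguous genomic unit, so each positive is
#' ranked against its "matched" negatives:
#' \itemize{
#'   \item \code{window} mode: a closed window of \code{window} bp on each
#'     side of every positive; overlapping windows on a chromosome are
#'     merged, and each merged window is one fold. A negative is kept iff
#'     it falls inside a merged window.
#'   \item \code{tad} mode: each TAD (half-open \code{[start, end)}
#'     intervals, BED-style 0-based) containing at least one positive is
#'     one fold; negatives inside positive-free TADs, or outside all TADs,
#'     are dropped.
#' }
#' Positives are always retained; a positive with no matched negatives (or
#' outside every TAD, which then forms a singleton fold) triggers a
#' warning.
#'
#' @param chrom,pos chromosome and 1-based position per variant.
#' @param labels binary labels per variant.
#' @param window half-width of the genomic window in bp (e.g. 1e5, 5e5,
#'   1e6). Exactly one of \code{window} and \code{tads} must be given.
#' @param tads data frame of TAD intervals with columns \code{chrom},
#'   \code{start}, \code{end} (and optionally \code{name}).
#' @return list with \code{selected} (row indices of retained variants, in
#'   input order) and \code{fold} (integer fold id per retained variant).
#' @export
matched_negative_folds <- function(chrom, pos, labels,
                                   window = NULL, tads = NULL) {
  labels <- as_binary_labels(labels)
  chrom <- as.character(chrom)
  stopifnot(length(chrom) == length(pos), length(pos) == length(labels))
  if (sum(labels == 1L) == 0L) stop("no positive variants", call. = FALSE)
  if (is.null(window) == is.null(tads)) {
    stop("give exactly one of 'window' or 'tads'", call. = FALSE)
  }

  if (!is.null(window)) {
    if (window <= 0) stop("'window' must be positive", call. = FALSE)
    ppos <- which(labels == 1L)
    fold_of <- rep(NA_integer_, length(labels))
    next_fold <- 0L
    for (ch in unique(chrom[ppos])[order(chrom_rank(unique(chrom[ppos])))]) {
      p <- pos[ppos[chrom[ppos] == ch]]
      win <- merge_intervals(pmax(1, p - window), p + window)
      on_ch <- which(chrom == ch)
      hit <- findInterval(pos[on_ch], win$start)
      inside <- hit >= 1L & pos[on_ch] <= win$end[pmax(hit, 1L)]
      fold_of[on_ch[inside]] <- next_fold + hit[inside]
      next_fold <- next_fold + nrow(win)
    }
    selected <- which(!is.na(fold_of) | labels == 1L)
    fold <- fold_of[selected]
  } else {
    req <- c("chrom", "start", "end")
    if (!all(req %in% names(tads))) {
      stop("'tads' needs columns chrom, start, end", call. = FALSE)
    }
    if (any(tads$start >= tads$end)) {
      stop("TAD intervals must have start < end", call. = FALSE)
    }
    tad_of <- rep(NA_integer_, length(labels))
    for (t in seq_len(nrow(tads))) {
      inside <- chrom == as.character(tads$chrom[t]) &
        pos > tads$start[t] & pos <= tads$end[t]
      tad_of[inside & is.na(tad_of)] <- t
    }
    pos_tads <- sort(unique(tad_of[labels == 1L & !is.na(tad_of)]))
    keep <- (labels == 1L) | (!is.na(tad_of) & tad_of %in% pos_tads)
    fold_map <- stats::setNames(seq_along(pos_tads), pos_tads)
    fold <- ifelse(is.na(tad_of), NA_integer_,
                   fold_map[as.character(tad_of)])
    orphan <- which(labels == 1L & is.na(fold))
    if (length(orphan) > 0L) {
      warning(sprintf("%d positive(s) outside every TAD kept as singleton folds",
                      length(orphan)), call. = FALSE)
      fold[orphan] <- length(pos_tads) + seq_along(orphan)
    }
    selected <- which(keep)
    fold <- fold[selected]
  }

  # renumber folds consecutively and warn about unmatched positives
  fold <- as.integer(factor(fold))
  lonely <- vapply(split(labels[selected] == 0L, fold), sum, 0) == 0
  if (any(lonely)) {
    warning(sprintf("%d fold(s) contain a positive with no matched negatives",
                    sum(lonely)), call. = FALSE)
  }
  list(selected = selected, fold = fold)
}

#' Progressive negative subsampling with preserved genomic coverage
#'
#' Selects \code{target} negatives by walking the position-sorted negatives
#' and taking every \code{s}-th one, \code{s = floor(n / target)}; the
#' genomic span of the negatives is preserved while their density shrinks.
#' With the positive count fixed, targets of \code{|P|}, \code{10 |P|},
#' \code{100 |P|} and \code{1000 |P|} produce the canonical 1:1, 1:10,
#' 1:100 and 1:1000 imbalance series.
#'
#' @param chrom,pos coordinates of the negative variants.
#' @param target number of negatives to keep.
#' @return integer vector of \code{target} indices into the input.
#' @export
progressive_subsample <- function(chrom, pos, target) {
  n <- length(pos)
  target <- check_count(target, "target")
  if (target > n) {
    stop(sprintf("target (%d) exceeds the number of negatives (%d)",
                 target, n), call. = FALSE)
  }
  ord <- genomic_order(chrom, pos)
  s <- n %/% target
  ord[seq(1L, by = s, length.out = target)]
}

#' Cross-validated hyper-ensemble scores
#'
#' For each fold, a hyper-ensemble is fitted on all other folds and scores
#' the held-out fold; the pooled out-of-fold scores are returned in input
#' order. SMOTE runs only on training-fold positives, so synthetics derived
#' from held-out positives can never leak into training. Per-fold training
#' row indices are recorded for the leakage audit
#' (\code{\link{cv_audit}}).
#'
#' @inheritParams smurf.default
#' @param folds integer fold id per variant, e.g. from
#'   \code{\link{cytoband_folds}} or \code{\link{matched_negative_folds}}.
#' @return object of class \code{"smurf_cv"}: \code{scores} (out-of-fold),
#'   \code{labels}, \code{folds}, \code{provenance} (per fold: training and
#'   test row indices), and the configuration.
#' @export
smurf_cv <- function(x, y, folds, n = 10L, f = 2L, m = 3L, k = 5L,
                     ntree = 10L, mtry = NULL, seed = NULL) {
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  folds <- as.integer(folds)
  stopifnot(length(y) == nrow(x), length(folds) == nrow(x))
  if (anyNA(folds)) stop("every variant needs a fold", call. = FALSE)
  ids <- sort(unique(folds))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  fold_seeds <- derive_seeds(seed, length(ids))

  scores <- rep(NA_real_, nrow(x))
  provenance <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    test <- which(folds == ids[j])
    train <- which(folds != ids[j])
    if (sum(y[train] == 1L) == 0L) {
      stop(sprintf("fold %d has zero training positives", ids[j]),
           call. = FALSE)
    }
    fit <- smurf.default(x[train, , drop = FALSE], y[train],
                         n = n, f = f, m = m, k = k, ntree = ntree,
                         mtry = mtry, seed = fold_seeds[j])
    scores[test] <- predict.smurf(fit, x[test, , drop = FALSE])
    provenance[[j]] <- list(fold = ids[j], train_rows = train,
                            test_rows = test)
  }

  structure(list(
    scores = scores, labels = y, folds = folds, provenance = provenance,
    config = list(n = n, f = f, m = m, k = k, ntree = ntree, seed = seed)
  ), class = "smurf_cv")
}

#' @export
print.smurf_cv <- function(x, ...) {
  cat(sprintf(
    "Out-of-fold hyper-ensemble scores: %d variants, %d folds\n",
    length(x$scores), length(x$provenance)))
  cat(sprintf("  AUPRC %.4f, AUROC %.4f\n",
              auprc(x$scores, x$labels), auroc(x$scores, x$labels)))
  invisible(x)
}

#' @export
summary.smurf_cv <- function(object, ...) {
  ranking_curves(object$scores, object$labels)
}

#' Audit a cross-validation run for train/test leakage
#'
#' Verifies, from the recorded provenance, that (i) every variant was
#' scored exactly once, (ii) no variant was scored by a model whose
#' training rows included it, and (iii) training and test rows jointly
#' cover the data in every fold. A planted leak — e.g. a held-out positive
#' duplicated into a fold's training rows — fails the audit.
#'
#' @param cv a \code{"smurf_cv"} object.
#' @return \code{TRUE} invisibly; stops with a message on any violation.
#' @export
cv_audit <- function(cv) {
  stopifnot(inherits(cv, "smurf_cv"))
  all_rows <- seq_along(cv$scores)
  tested <- sort(unlist(lapply(cv$provenance, `[[`, "test_rows")))
  if (!identical(tested, all_rows)) {
    stop("audit failed: variants not scored exactly once", call. = FALSE)
  }
  for (p in cv$provenance) {
    if (length(intersect(p$train_rows, p$test_rows)) > 0L) {
      stop(sprintf(
        "audit failed: fold %d scored variants present in its training set",
        p$fold), call. = FALSE)
    }
    if (!setequal(c(p$train_rows, p$test_rows), all_rows)) {
      stop(sprintf("audit failed: fold %d does not partition the data",
                   p$fold), call. = FALSE)
    }
  }
  if (anyNA(cv$scores)) {
    stop("audit failed: unscored variants", call. = FALSE)
  }
  invisible(TRUE)
}
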