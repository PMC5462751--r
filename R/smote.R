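#' Nearest positive neighbours of a positive example
#'
#' Returns the \code{k} positives closest (in Euclidean distance) to the
#' positive in row \code{i}, excluding that row itself. When fewer than
#' \code{k} other positives exist, all of them are returned. Ties at equal
#' distance are broken by ascending row index, so the result is
#' deterministic.
#'
#' @param x numeric matrix (or data frame) of positive feature vectors,
#'   one row per example.
#' @param i row index of the query positive.
#' @param k number of neighbours requested.
#' @return matrix of the neighbour rows, closest first, with the original
#'   row indices in attribute \code{"index"}.
#' @examples
#' p <- matrix(c(0, 1, 3), ncol = 1)
#' knn_positive_neighbors(p, 1, 2)
#' @export
knn_positive_neighbors <- function(x, i, k) {
  x <- as_feature_matrix(x)
  k <- check_count(k, "k")
  np <- nrow(x)
  if (np < 2L) {
    stop("need at least 2 positives to find neighbours", call. = FALSE)
  }
  i <- check_count(i, "i")
  if (i > np) stop("'i' is out of range", call. = FALSE)
  d2 <- rowSums((x - matrix(x[i, ], np, ncol(x), byrow = TRUE))^2)
  ord <- order(d2, seq_len(np))       # stable: ties by ascending index
  ord <- ord[ord != i]
  idx <- ord[seq_len(min(k, np - 1L))]
  out <- x[idx, , drop = FALSE]
  attr(out, "index") <- idx
  out
}

#' SMOTE: synthetic minority oversampling by k-NN interpolation
#'
#' Generates \code{f} synthetic examples per positive. For each positive
#' \eqn{x}, one of its \eqn{k} nearest positive neighbours \eqn{x'} is drawn
#' uniformly and a synthetic point is placed on the connecting segment,
#' \deqn{x_s = x + \lambda (x' - x), \qquad \lambda \sim U[0, 1],}
#' with a fresh neighbour and a fresh \eqn{\lambda} for every synthetic
#' example. The output therefore has exactly \code{f * nrow(x)} rows.
#'
#' With a single positive no interpolation is possible; the point is
#' duplicated \code{f} times with a warning. When fewer than \code{k} other
#' positives exist, all of them serve as the neighbour pool.
#'
#' @param x numeric matrix of positive feature vectors (rows = examples).
#' @param f oversampling factor: synthetic examples per positive.
#' @param k number of nearest neighbours to interpolate towards.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return numeric matrix of \code{f * nrow(x)} synthetic rows. Attribute
#'   \code{"provenance"} is a data frame with, per synthetic row, the source
#'   row \code{source}, the chosen neighbour \code{neighbor} and the
#'   interpolation weight \code{lambda}.
#' @examples
#' p <- matrix(c(0, 1), ncol = 1)
#' smote(p, f = 3, k = 1, seed = 1)
#' @export
smote <- function(x, f = 1L, k = 5L, seed = NULL) {
  x <- as_feature_matrix(x)
  f <- check_count(f, "f")
  k <- check_count(k, "k")
  np <- nrow(x)
  if (np == 0L) stop("empty positive set", call. = FALSE)

  if (np == 1L) {
    warning("single positive example: emitting exact duplicates",
            call. = FALSE)
    out <- x[rep(1L, f), , drop = FALSE]
    attr(out, "provenance") <- data.frame(
      source = rep(1L, f), neighbor = rep(1L, f), lambda = rep(0, f))
    rownames(out) <- NULL
    return(out)
  }

  kk <- min(k, np - 1L)
  # neighbour index table, one row per positive
  nn <- matrix(0L, np, kk)
  for (i in seq_len(np)) {
    nn[i, ] <- attr(knn_positive_neighbors(x, i, kk), "index")
  }

  with_seed(seed, {
    n_syn <- f * np
    src <- rep(seq_len(np), each = f)
    nbr <- integer(n_syn)
    lam <- numeric(n_syn)
    out <- matrix(0, n_syn, ncol(x))
    for (s in seq_len(n_syn)) {
      i <- src[s]
      nbr[s] <- nn[i, sample.int(kk, 1L)]
      lam[s] <- stats::runif(1L)
      out[s, ] <- x[i, ] + lam[s] * (x[nbr[s], ] - x[i, ])
    }
    colnames(out) <- colnames(x)
    attr(out, "provenance") <- data.frame(
      source = src, neighbor = nbr, lambda = lam)
    out
  })
}
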