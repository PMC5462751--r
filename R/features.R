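# Chromatin-effect feature transforms.
#
# A deep-learning chromatin model scores two 1000-bp sequences centred on
# a variant (reference vs alternative allele), yielding one probability
# pair per chromatin feature. Two complementary summaries are derived per
# pair: the absolute probability difference (diff, bounded by 1) and the
# absolute log-odds change (logfold, unbounded near the probability
# extremes). Both are invariant to swapping the alleles and to the
# complement transform p -> 1 - p.

#' diff / logfold transform of an allele probability pair
#'
#' \deqn{diff = |p_{ref} - p_{alt}|}
#' \deqn{logfold = \left| \log\frac{p_{ref}}{1-p_{ref}} -
#'   \log\frac{p_{alt}}{1-p_{alt}} \right|}
#' Natural logarithms are used; the base only rescales the feature and is
#' irrelevant after standardization. Probabilities are clipped to
#' \code{[eps, 1 - eps]} so the logits stay finite.
#'
#' @param p_ref,p_alt probabilities in \eqn{[0, 1]} (vectorised).
#' @param eps clipping bound, default \code{1e-6}.
#' @return data frame with columns \code{diff} and \code{logfold}.
#' @examples
#' diff_logfold(0.9, 0.5) # diff 0.4, logfold log(9)
#' @export
diff_logfold <- function(p_ref, p_alt, eps = 1e-6) {
  if (anyNA(p_ref) || anyNA(p_alt) ||
      any(p_ref < 0 | p_ref > 1) || any(p_alt < 0 | p_alt > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(p_ref) != length(p_alt)) {
    stop("p_ref and p_alt differ in length", call. = FALSE)
  }
  pr <- pmin(pmax(p_ref, eps), 1 - eps)
  pa <- pmin(pmax(p_alt, eps), 1 - eps)
  logit <- function(p) log(p / (1 - p))
  data.frame(diff = abs(pr - pa), logfold = abs(logit(pr) - logit(pa)))
}

#' Assemble the chromatin-effect feature matrix
#'
#' Converts per-variant reference/alternative probability matrices into the
#' model's feature matrix: all diff columns, then all logfold columns, then
#' any conservation columns — a fixed, documented order, so serialised
#' matrices are reproducible. With 919 chromatin features this yields 1838
#' transform columns, or 1842 with the four standard conservation scores
#' appended.
#'
#' @param p_ref,p_alt numeric matrices, variants in rows and chromatin
#'   features in columns, with identical dimensions.
#' @param conservation optional numeric matrix of per-variant conservation
#'   scores (e.g. PhastCons, PhyloP, GERP++ neutral and rejected
#'   substitution), appended unchanged.
#' @param eps clipping bound passed to \code{\link{diff_logfold}}.
#' @return numeric matrix with \code{2 * ncol(p_ref) + ncol(conservation)}
#'   columns named \code{diff_*}, \code{logfold_*}, then the conservation
#'   names.
#' @export
chromatin_features <- function(p_ref, p_alt, conservation = NULL,
                               eps = 1e-6) {
  p_ref <- as_feature_matrix(p_ref)
  p_alt <- as_feature_matrix(p_alt)
  if (!identical(dim(p_ref), dim(p_alt))) {
    stop("p_ref and p_alt must have identical dimensions", call. = FALSE)
  }
  ids <- colnames(p_ref)
  tf <- diff_logfold(as.vector(p_ref), as.vector(p_alt), eps = eps)
  d <- matrix(tf$diff, nrow(p_ref), ncol(p_ref))
  l <- matrix(tf$logfold, nrow(p_ref), ncol(p_ref))
  colnames(d) <- paste0("diff_", ids)
  colnames(l) <- paste0("logfold_", ids)
  out <- cbind(d, l)
  if (!is.null(conservation)) {
    conservation <- as_feature_matrix(conservation)
    if (nrow(conservation) != nrow(p_ref)) {
      stop("conservation rows do not match the variants", call. = FALSE)
    }
    out <- cbind(out, conservation)
  }
  out
}

#' Standardize feature columns to zero mean and unit variance
#'
#' Population-variance scaling (divide by the SD computed with \code{n} in
#' the denominator). Constant columns are mapped to zero with a recorded
#' scale of 1. The fitted centre and scale are attached as attributes so
#' the same transform can be applied to new variants
#' (\code{center}/\code{scale} arguments), e.g. when standardization is
#' fitted on training data only.
#'
#' @param x numeric feature matrix.
#' @param center,scale optional precomputed per-column centre and scale;
#'   when given, they are applied instead of being estimated.
#' @return standardized matrix with attributes \code{"center"} and
#'   \code{"scale"}.
#' @seealso \code{\link{unstandardize}}
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L && is.null(center)) {
    stop("need at least 2 rows to estimate the standardization",
         call. = FALSE)
  }
  if (is.null(center) != is.null(scale)) {
    stop("give both 'center' and 'scale', or neither", call. = FALSE)
  }
  if (is.null(center)) {
    center <- colMeans(x)
    n <- nrow(x)
    scale <- sqrt(pmax(colMeans(x^2) - center^2, 0))  # population SD
    scale[scale < .Machine$double.eps^0.5 * pmax(1, abs(center))] <- 1
  }
  z <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

#' @rdname standardize
#' @param z a matrix produced by \code{standardize} (or any matrix, with
#'   explicit \code{center}/\code{scale}).
#' @export
unstandardize <- function(z, center = attr(z, "center"),
                          scale = attr(z, "scale")) {
  if (is.null(center) || is.null(scale)) {
    stop("no standardization parameters available", call. = FALSE)
  }
  out <- sweep(sweep(z, 2L, scale, "*"), 2L, center, "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}
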