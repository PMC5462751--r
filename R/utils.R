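# Internal helpers: seeded evaluation and seed derivation.
#
# All user-facing functions take an optional `seed`; randomness is always
# routed through `with_seed()` so the caller's RNG state is left untouched,
# and composite procedures derive independent sub-seeds with
# `derive_seeds()` so that per-partition / per-fold work is reproducible
# regardless of execution order.

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# n sub-seeds < 2^31, a deterministic function of the master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (!is.numeric(x)) {
    stop("features must be numeric", call. = FALSE)
  }
  if (anyNA(x)) stop("features contain missing values", call. = FALSE)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  x
}

# coerce labels to a 0/1 integer vector
as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) y <- as.numeric(y)
  if (is.logical(y)) y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("labels must be binary (0 = non-deleterious, 1 = deleterious)",
         call. = FALSE)
  }
  as.integer(y)
}

check_count <- function(value, name, min = 1L) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value) ||
      value < min || value != as.integer(value)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(value)
}
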