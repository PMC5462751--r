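# Synthetic imbalanced variant data.
#
# The generator emulates the *structure* of a genome-wide variant scoring
# problem — a tiny positive class, a huge negative background, genomic
# coordinates and cytogenetic bands — without any external resource.
# Negatives are a standard multivariate Gaussian; positives come from a
# small number of shifted Gaussian sub-clusters, so SMOTE's k-NN locality
# is geometrically meaningful. Coordinates are synthetic: equal-length
# chromosomes subdivided into equal-width bands.

#' Simulate an imbalanced labelled variant set
#'
#' @param n_pos number of positives (deleterious variants), at least 2.
#' @param n_neg number of negatives, at least \code{n_pos}.
#' @param d feature dimensionality.
#' @param separation distance of each positive sub-cluster centroid from
#'   the negative centroid, in units of within-class SD. 0 means no signal.
#' @param n_clusters_pos number of positive sub-clusters.
#' @param n_chrom,bands_per_chrom coordinate scaffold: chromosomes
#'   \code{chr1..chrN}, each with this many equal-width bands.
#' @param chrom_length chromosome length in bp.
#' @param seed optional integer seed.
#' @return data frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{band}, \code{label} (1 = deleterious) and features
#'   \code{f1..fd}. Positives occupy the first \code{n_pos} rows.
#' @examples
#' head(simulate_variants(n_pos = 5, n_neg = 50, seed = 1))
#' @export
simulate_variants <- function(n_pos = 50L, n_neg = 5000L, d = 10L,
                              separation = 2.5, n_clusters_pos = 3L,
                              n_chrom = 5L, bands_per_chrom = 8L,
                              chrom_length = 1.2e8, seed = NULL) {
  n_pos <- check_count(n_pos, "n_pos", min = 2L)
  n_neg <- check_count(n_neg, "n_neg", min = n_pos)
  d <- check_count(d, "d")
  n_clusters_pos <- check_count(n_clusters_pos, "n_clusters_pos")
  n_chrom <- check_count(n_chrom, "n_chrom")
  bands_per_chrom <- check_count(bands_per_chrom, "bands_per_chrom")
  if (!is.numeric(separation) || separation < 0) {
    stop("'separation' must be >= 0", call. = FALSE)
  }

  with_seed(seed, {
    # sparse, axis-aligned centroids: cluster j shifts feature ((j-1) mod d)+1
    # by `separation`, mimicking annotation data where deleterious variants
    # deviate strongly in a few features rather than diffusely in all
    centroids <- matrix(0, n_clusters_pos, d)
    for (j in seq_len(n_clusters_pos)) {
      centroids[j, (j - 1L) %% d + 1L] <- separation
    }

    cl <- sample.int(n_clusters_pos, n_pos, replace = TRUE)
    xp <- centroids[cl, , drop = FALSE] +
      matrix(stats::rnorm(n_pos * d), n_pos, d)
    xn <- matrix(stats::rnorm(n_neg * d), n_neg, d)
    x <- rbind(xp, xn)
    colnames(x) <- paste0("f", seq_len(d))

    n <- n_pos + n_neg
    chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
    pos <- sample.int(chrom_length, n, replace = TRUE)
    band_width <- ceiling(chrom_length / bands_per_chrom)
    band <- paste0(chrom, "_b", (pos - 1L) %/% band_width + 1L)

    data.frame(
      id = sprintf("v%0*d", nchar(n), seq_len(n)),
      chrom = chrom, pos = pos, band = band,
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      x, stringsAsFactors = FALSE)
  })
}

#' Band intervals of the synthetic coordinate scaffold
#'
#' BED-style half-open intervals of the equal-width cytogenetic bands used
#' by \code{\link{simulate_variants}}; useful for exporting the band
#' definitions alongside a simulated variant table.
#'
#' @inheritParams simulate_variants
#' @return data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name} (0-based half-open).
#' @export
simulated_band_table <- function(n_chrom = 5L, bands_per_chrom = 8L,
                                 chrom_length = 1.2e8) {
  band_width <- ceiling(chrom_length / bands_per_chrom)
  grid <- expand.grid(b = seq_len(bands_per_chrom), c = seq_len(n_chrom))
  data.frame(
    chrom = paste0("chr", grid$c),
    start = (grid$b - 1) * band_width,
    end = pmin(grid$b * band_width, chrom_length),
    name = paste0("chr", grid$c, "_b", grid$b),
    stringsAsFactors = FALSE)
}

#' Simulate reference/alternative chromatin probability pairs
#'
#' Emulates the output of a chromatin-effect model scored on both alleles:
#' per variant and chromatin feature, a Beta-distributed baseline
#' probability for the reference allele, and an alternative-allele
#' probability equal to the baseline plus logit-scale noise. For positives
#' a random fraction \code{effect_fraction} of the features additionally
#' receives a logit shift of \code{effect_size} (random sign). With
#' \code{effect_fraction = 0} the two classes are distributionally
#' identical.
#'
#' @param n_pos,n_neg class sizes.
#' @param n_features number of chromatin features.
#' @param effect_fraction fraction of features perturbed in positives, in
#'   \eqn{[0, 1]}.
#' @param effect_size logit-scale shift applied to perturbed features.
#' @param noise_sd SD of the logit-scale noise shared by both classes.
#' @param seed optional integer seed.
#' @return list with matrices \code{p_ref}, \code{p_alt} (rows = variants,
#'   positives first), \code{label}, and the logical matrix
#'   \code{perturbed} marking which entries carry an effect.
#' @export
simulate_chromatin_pairs <- function(n_pos = 50L, n_neg = 500L,
                                     n_features = 20L,
                                     effect_fraction = 0.3,
                                     effect_size = 2, noise_sd = 0.1,
                                     seed = NULL) {
  n_pos <- check_count(n_pos, "n_pos")
  n_neg <- check_count(n_neg, "n_neg")
  n_features <- check_count(n_features, "n_features")
  if (effect_fraction < 0 || effect_fraction > 1) {
    stop("'effect_fraction' must lie in [0, 1]", call. = FALSE)
  }

  with_seed(seed, {
    n <- n_pos + n_neg
    label <- rep(c(1L, 0L), c(n_pos, n_neg))
    p_ref <- matrix(stats::rbeta(n * n_features, 2, 2), n, n_features)
    logit <- function(p) log(p / (1 - p))
    expit <- function(z) 1 / (1 + exp(-z))
    z <- logit(p_ref) +
      matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)

    perturbed <- matrix(FALSE, n, n_features)
    n_eff <- round(effect_fraction * n_features)
    if (n_eff > 0L) {
      for (i in seq_len(n_pos)) {
        j <- sample.int(n_features, n_eff)
        z[i, j] <- z[i, j] + sample(c(-1, 1), n_eff, replace = TRUE) *
          effect_size
        perturbed[i, j] <- TRUE
      }
    }
    p_alt <- expit(z)
    colnames(p_ref) <- colnames(p_alt) <- paste0("cf", seq_len(n_features))
    list(p_ref = p_ref, p_alt = p_alt, label = label,
         perturbed = perturbed)
  })
}
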