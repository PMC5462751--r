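# Native exchange formats.
#
# The method consumes feature matrices, not genotypes, so the native
# format is a plain TSV variant table rather than VCF: one row per
# variant with id, coordinates, an optional cytogenetic band, a binary
# label and real-valued feature columns. Interval tables (cytobands,
# TADs) are BED-like TSVs. Every file written by the package embeds the
# fully resolved configuration and seed as "# key=value" comment lines,
# sufficient to reproduce the run.

RESERVED_COLUMNS <- c("id", "chrom", "pos", "band", "label", "score",
                      "fold")

config_header <- function(config) {
  if (is.null(config) || length(config) == 0L) return(character(0))
  vals <- vapply(config, function(v) paste(format(v), collapse = ","), "")
  sprintf("# %s=%s", names(config), vals)
}

write_tsv_with_header <- function(df, path, config = NULL) {
  # %.17g makes the double -> text -> double round trip bitwise exact
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant table
#'
#' Reads the native TSV format: header columns \code{id}, \code{chrom},
#' \code{pos} (1-based), optional \code{band}, \code{label} (0/1, NA
#' allowed only when \code{allow_na_labels} for prediction inputs), then
#' any number of numeric feature columns. Lines starting with \code{#} are
#' configuration comments and are skipped.
#'
#' @param path path of the TSV file.
#' @param allow_na_labels allow missing labels (prediction input).
#' @return data frame; the feature column names are attached as attribute
#'   \code{"features"}.
#' @export
read_variant_table <- function(path, allow_na_labels = FALSE) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "chrom", "pos", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate variant id(s) in '%s': %s", path,
                 paste(utils::head(dup, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.numeric(df$pos) || any(df$pos < 1, na.rm = TRUE)) {
    stop("'pos' must be 1-based integer positions", call. = FALSE)
  }
  bad_label <- !(df$label %in% c(0L, 1L) | is.na(df$label))
  if (any(bad_label)) {
    stop(sprintf("non-binary label at data line %s",
                 paste(utils::head(which(bad_label), 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(df$label) && !allow_na_labels) {
    stop("missing labels are only allowed for prediction input",
         call. = FALSE)
  }
  features <- setdiff(names(df), RESERVED_COLUMNS)
  if (length(features) > 0L) {
    numeric_ok <- vapply(df[features], is.numeric, TRUE)
    if (!all(numeric_ok)) {
      stop(sprintf("non-numeric feature column(s): %s",
                   paste(features[!numeric_ok], collapse = ", ")),
           call. = FALSE)
    }
    if (anyNA(df[features])) {
      stop("feature columns contain missing values", call. = FALSE)
    }
  }
  attr(df, "features") <- features
  df
}

#' @rdname read_variant_table
#' @param df variant data frame as produced by
#'   \code{\link{simulate_variants}} or \code{read_variant_table}.
#' @param config optional named list written as \code{# key=value} header
#'   lines.
#' @export
write_variant_table <- function(df, path, config = NULL) {
  write_tsv_with_header(df, path, config)
}

#' Feature columns of a variant table
#'
#' All columns that are not bookkeeping columns (\code{id}, \code{chrom},
#' \code{pos}, \code{band}, \code{label}, \code{score}, \code{fold}).
#'
#' @param df a variant data frame.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(df) {
  setdiff(names(df), RESERVED_COLUMNS)
}

#' Read a BED-like interval table
#'
#' Tab-separated \code{chrom}, \code{start}, \code{end}, \code{name}
#' (0-based half-open intervals). A header line is optional and detected
#' from the first field; \code{#} comment lines are skipped.
#'
#' @param path path of the interval file.
#' @return data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}.
#' @export
read_intervals <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  if (length(first) == 0L) stop("empty interval file", call. = FALSE)
  has_header <- grepl("^(chrom|chr\\b|#?chrom)", first[1L],
                      ignore.case = TRUE) &&
    !grepl("^chr[0-9XYM]", first[1L])
  df <- utils::read.delim(path, header = has_header, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 3L) {
      stop("interval file needs columns chrom, start, end", call. = FALSE)
    }
    names(df)[1:3] <- c("chrom", "start", "end")
    if (ncol(df) >= 4L) names(df)[4L] <- "name"
  }
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("interval file needs columns chrom, start, end", call. = FALSE)
  }
  if (!("name" %in% names(df))) {
    df$name <- sprintf("iv%d", seq_len(nrow(df)))
  }
  if (any(df$start >= df$end)) {
    stop(sprintf("interval with start >= end at record %s",
                 paste(utils::head(which(df$start >= df$end), 5L),
                       collapse = ", ")), call. = FALSE)
  }
  df[c("chrom", "start", "end", "name")]
}

#' @rdname read_intervals
#' @param df interval data frame.
#' @param path output path.
#' @param config optional named list written as comment header.
#' @export
write_intervals <- function(df, path, config = NULL) {
  write_tsv_with_header(df[c("chrom", "start", "end", "name")], path,
                        config)
}

#' Write / read a score table
#'
#' Two-plus-column TSV of variant ids and hyper-ensemble scores, with any
#' further columns (e.g. \code{label}, \code{fold}) preserved, and the
#' resolved configuration embedded as comment lines.
#'
#' @param df data frame with at least \code{id} and \code{score} columns.
#' @param path file path.
#' @param config optional named list written as comment header.
#' @export
write_score_table <- function(df, path, config = NULL) {
  stopifnot(all(c("id", "score") %in% names(df)))
  write_tsv_with_header(df, path, config)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "score") %in% names(df))) {
    stop(sprintf("'%s' must have columns id and score", path),
         call. = FALSE)
  }
  df
}

#' Minimal VCF import
#'
#' Convenience import of CHROM/POS/ID from a (sites-only) VCF; features
#' must be joined by id afterwards. Not a VCF annotation engine.
#'
#' @param path path of an uncompressed VCF file.
#' @return data frame with columns \code{id}, \code{chrom}, \code{pos}.
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stop("VCF contains no records", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed VCF record at data line %d", bad[1L]),
         call. = FALSE)
  }
  data.frame(
    id = vapply(parts, `[[`, "", 3L),
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE)
}
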