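#' Expression matrix container
#'
#' A light container for a feature-by-sample expression matrix together with
#' its cohort label (`tumor` or `control`) and measurement scale (`raw`
#' normalized units such as RPKM/RPM, or `log2` after [log2_transform()]).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Must carry unique rownames (feature ids) and colnames (sample ids).
#' @param cohort `"tumor"` or `"control"`.
#' @param scale `"raw"` or `"log2"`. Raw values must be non-negative.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cohort = c("tumor", "control"),
                              scale = c("raw", "log2")) {
  cohort <- match.arg(cohort)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have feature rownames and sample colnames")
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyNA(values)) stop("missing values are not allowed")
  if (scale == "raw" && nrow(values) > 0 && min(values) < 0)
    stop("raw-scale expression must be non-negative")
  structure(list(values = values, cohort = cohort, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s, %s scale)\n",
              nrow(x$values), ncol(x$values), x$cohort, x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a feature-by-sample expression TSV
#'
#' Expects a rectangular tab-separated file whose header row names the
#' samples and whose first column holds feature ids.  Values are read as raw
#' (pre-log) normalized expression.  Ragged rows, duplicate feature ids and
#' non-numeric cells are rejected with the offending row/column named.
#'
#' @param path Path to the TSV file.
#' @param cohort Cohort label recorded on the returned matrix.
#' @return An [expression_matrix()] with `scale = "raw"`.
#' @export
read_expression_tsv <- function(path, cohort = c("tumor", "control")) {
  cohort <- match.arg(cohort)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  body <- fields[-1L]
  lens <- lengths(body)
  if (any(lens != n_col))
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 which(lens != n_col)[1L] + 1L, n_col,
                 lens[lens != n_col][1L]))
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1L])
  # locale-independent numeric parse; flag the first bad cell
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                 dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                   feature_ids[i], sample_ids[j], body[[i]][j + 1L]))
    }
    vals[i, ] <- v
  }
  expression_matrix(vals, cohort = cohort, scale = "raw")
}

#' Write an expression matrix as TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform raw expression
#'
#' Applies `log2(x + pseudocount)` elementwise.  The pseudocount (default 1)
#' keeps the ubiquitous zeros of miRNA-seq finite and makes the transform
#' invertible (`x = 2^y - pseudocount`).  Double transformation is refused.
#'
#' @param m An [expression_matrix()] with `scale = "raw"`.
#' @param pseudocount Positive offset added before taking logs.
#' @return The transformed matrix with `scale = "log2"`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale == "log2")
    stop("matrix is already on the log2 scale; refusing to transform twice")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("`pseudocount` must be positive")
  m$values <- log2(m$values + pseudocount)
  m$scale <- "log2"
  m
}

#' Remove very lowly expressed features
#'
#' A feature is removed when it fails either criterion: its fraction of
#' nonzero samples is below `min_nonzero_frac`, or its mean raw expression is
#' below `min_mean_raw`.  Applied on the raw scale, before log transform.
#'
#' @param m An [expression_matrix()] with `scale = "raw"`.
#' @param min_nonzero_frac Minimum fraction of samples with nonzero
#'   expression, in `[0, 1]`.
#' @param min_mean_raw Minimum mean raw expression, non-negative.
#' @return A list with elements `matrix` (the filtered
#'   [expression_matrix()], feature order preserved) and `removed_ids`.
#' @export
filter_low_expressed <- function(m, min_nonzero_frac = 0.1,
                                 min_mean_raw = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "raw")
    stop("low-expression filtering operates on the raw scale")
  if (!is.numeric(min_nonzero_frac) || min_nonzero_frac < 0 ||
      min_nonzero_frac > 1)
    stop("`min_nonzero_frac` must be in [0, 1]")
  if (!is.numeric(min_mean_raw) || min_mean_raw < 0)
    stop("`min_mean_raw` must be non-negative")
  nonzero <- rowMeans(m$values != 0)
  means <- rowMeans(m$values)
  keep <- nonzero >= min_nonzero_frac & means >= min_mean_raw
  removed <- rownames(m$values)[!keep]
  m$values <- m$values[keep, , drop = FALSE]
  list(matrix = m, removed_ids = removed)
}

#' Subset an expression matrix to a fixed feature list
#'
#' Used to carry the tumor-derived low-expression feature list over to the
#' control cohort so both cohorts are scored on identical features.
#'
#' @param m An [expression_matrix()].
#' @param feature_ids Features to keep, in the given order.
#' @export
subset_features <- function(m, feature_ids) {
  stopifnot(inherits(m, "expression_matrix"))
  missing <- setdiff(feature_ids, rownames(m$values))
  if (length(missing))
    stop("features not present in matrix: ",
         paste(head(missing, 3), collapse = ", "))
  m$values <- m$values[feature_ids, , drop = FALSE]
  m
}

#' Resample a cohort to a target size
#'
#' Draws samples (columns) with replacement to match a target cohort size,
#' as used to put tumor and control cohorts on an equal footing before
#' counting bimodal features.  A without-replacement subsample mode is
#' available.
#'
#' @param m An [expression_matrix()].
#' @param target_n Number of samples to draw (at least 2).
#' @param seed Integer seed; the draw is fully determined by it.
#' @param replace Draw with replacement (bootstrap, default) or without.
#' @return An [expression_matrix()] with exactly `target_n` columns; resampled
#'   sample ids are suffixed to remain unique.
#' @export
bootstrap_match <- function(m, target_n, seed, replace = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (ncol(m$values) == 0L) stop("cannot resample an empty matrix")
  if (target_n < 2L) stop("`target_n` must be at least 2")
  if (!replace && target_n > ncol(m$values))
    stop("without replacement, `target_n` cannot exceed the sample count")
  set.seed(seed)
  idx <- sample.int(ncol(m$values), target_n, replace = replace)
  vals <- m$values[, idx, drop = FALSE]
  colnames(vals) <- paste0(colnames(m$values)[idx], ".b", seq_len(target_n))
  m$values <- vals
  m
}
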