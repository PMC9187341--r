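#' Correlate feature expression with drug potency across cell lines
#'
#' For each drug, computes the Pearson correlation between the feature's
#' per-cell-line expression and the natural log of the drug's IC50
#' (pairwise-complete: cell lines missing a drug's IC50 are dropped for that
#' drug).  A negative correlation means the drug is more potent (lower
#' IC50) in high-expressing lines.
#'
#' @param mirna_expr Named numeric vector: expression per cell line.
#' @param ic50_table Matrix or data.frame of IC50 values in micromolar
#'   (rows = cell lines, columns = drugs, `NA` = not measured).  IC50 values
#'   must be positive.
#' @param min_lines Minimum usable cell lines per drug (default 3); drugs
#'   below it are reported with `r = NA` and a warning.
#' @return Data.frame with `drug_id`, `n_cell_lines_used`, `r` and
#'   `direction` (`effective_in_high` for r < 0, `ineffective_in_high` for
#'   r > 0).
#' @export
correlate_drugs <- function(mirna_expr, ic50_table, min_lines = 3) {
  if (is.null(names(mirna_expr))) stop("`mirna_expr` must be named by cell line")
  ic50 <- as.matrix(ic50_table)
  if (any(ic50 <= 0, na.rm = TRUE))
    stop("IC50 values must be positive (micromolar concentrations)")
  common <- intersect(names(mirna_expr), rownames(ic50))
  if (length(common) < min_lines)
    stop("fewer than ", min_lines, " cell lines shared between expression ",
         "and IC50 tables")
  expr <- mirna_expr[common]
  log_ic50 <- log(ic50[common, , drop = FALSE])
  out <- lapply(colnames(log_ic50), function(drug) {
    y <- log_ic50[, drug]
    ok <- is.finite(y) & is.finite(expr)
    n <- sum(ok)
    r <- NA_real_
    if (n < min_lines) {
      warning("drug '", drug, "' has only ", n,
              " usable cell lines; excluded")
    } else if (stats::sd(expr[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("drug '", drug, "' has constant expression or IC50; ",
              "correlation undefined")
    } else {
      r <- cor(expr[ok], y[ok])
    }
    data.frame(drug_id = drug, n_cell_lines_used = n, r = r,
               direction = if (is.na(r)) NA_character_
                           else if (r < 0) "effective_in_high"
                           else "ineffective_in_high",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank drugs by expression-IC50 correlation
#'
#' The `top_effective` list holds the `k` drugs with the most negative
#' correlations (most potent in high-expressing lines), sorted ascending by
#' `r`; `top_ineffective` holds the most positive.  Drugs with undefined
#' correlation are excluded; ties are broken by drug id.
#'
#' @param correlations Data.frame from [correlate_drugs()].
#' @param k List length (default 15).
#' @return List with data.frames `top_effective` and `top_ineffective`.
#' @export
rank_drugs <- function(correlations, k = 15) {
  ok <- correlations[!is.na(correlations$r), , drop = FALSE]
  eff <- ok[order(ok$r, ok$drug_id), , drop = FALSE]
  ineff <- ok[order(-ok$r, ok$drug_id), , drop = FALSE]
  top_eff <- head(eff, k)
  if (nrow(top_eff) && any(top_eff$r >= 0))
    warning("fewer than ", k, " drugs with negative correlation; the ",
            "effective list includes non-negative correlations")
  rownames(top_eff) <- NULL
  top_ineff <- head(ineff, k)
  rownames(top_ineff) <- NULL
  list(top_effective = top_eff, top_ineffective = top_ineff)
}

#' Combined module expression across cell lines
#'
#' Summarizes a multi-feature module as the mean of the member features'
#' z-scores per cell line, for correlating a whole module (rather than a
#' single feature) with drug response.
#'
#' @param expr_matrix Numeric matrix, cell lines in rows, features in
#'   columns.
#' @param features Module member columns to combine.
#' @return Named numeric vector (one combined score per cell line).
#' @export
module_expression_score <- function(expr_matrix, features) {
  missing <- setdiff(features, colnames(expr_matrix))
  if (length(missing))
    stop("features not in expression matrix: ",
         paste(head(missing, 3), collapse = ", "))
  z <- scale(expr_matrix[, features, drop = FALSE])
  setNames(rowMeans(z), rownames(expr_matrix))
}
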