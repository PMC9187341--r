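#' Stratify samples by module expression
#'
#' Partitions the samples into two groups using the expression of a set of
#' module features: agglomerative hierarchical clustering with Manhattan
#' (L1) dissimilarity and complete linkage, cut at two groups.  The group
#' with the higher mean module expression is labeled `"high"`.  Samples are
#' put in a canonical (sorted-id) order before clustering so the partition
#' does not depend on input column order.  An alternative `"mixture"` rule
#' assigns each sample by majority membership in the upper k-means component
#' across the module's features.
#'
#' @param m An [expression_matrix()] (log2 scale) of the tumor cohort.
#' @param module_features Features defining the stratification.
#' @param method `"hclust"` (default) or `"mixture"`.
#' @return Named factor (levels `low`, `high`), one entry per sample.
#' @export
stratify_hierarchical <- function(m, module_features,
                                  method = c("hclust", "mixture")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expression_matrix"))
  if (ncol(m$values) < 2L) stop("need at least 2 samples to stratify")
  missing <- setdiff(module_features, rownames(m$values))
  if (length(missing))
    stop("module features not in matrix: ",
         paste(head(missing, 3), collapse = ", "))
  vals <- m$values[module_features, , drop = FALSE]
  vals <- vals[, order(colnames(vals)), drop = FALSE]   # canonical order
  if (method == "hclust") {
    d <- dist(t(vals), method = "manhattan")
    grp <- cutree(hclust(d, method = "complete"), k = 2)
  } else {
    # majority membership in the upper component, feature by feature
    upper <- vapply(seq_len(nrow(vals)), function(i) {
      km <- kmeans_recluster(vals[i, ])
      km$assignments == 2L
    }, logical(ncol(vals)))
    grp <- ifelse(rowMeans(upper) > 0.5, 2L, 1L)
    names(grp) <- colnames(vals)
  }
  means <- tapply(colMeans(vals), grp, mean)
  high_grp <- as.integer(names(means)[which.max(means)])
  lab <- factor(ifelse(grp == high_grp, "high", "low"),
                levels = c("low", "high"))
  names(lab) <- names(grp)
  lab[colnames(m$values)]   # report in original sample order
}

#' Cox proportional-hazards comparison of two patient groups
#'
#' Fits a proportional-hazards model with the binary group label as the
#' only covariate (Breslow tie handling).  Reports the hazard ratio of the
#' second level (`high`) versus the first (`low`), its 95% confidence
#' interval from the coefficient standard error, the Wald test p-value, and
#' each group's Kaplan–Meier median survival with confidence interval.
#'
#' @param group_labels Named factor from [stratify_hierarchical()] (or any
#'   two-level factor named by sample id).
#' @param clinical Data.frame with columns `sample_id`, `time_days`,
#'   `event` (1 = death observed, 0 = censored).
#' @return A `stratification_result`: list with `group_labels`, `hr`,
#'   `ci_low`, `ci_high`, `wald_p`, `median_survival` (per-group data.frame)
#'   and `n_per_group`.
#' @export
fit_cox <- function(group_labels, clinical) {
  req <- c("sample_id", "time_days", "event")
  if (!all(req %in% names(clinical)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))
  ids <- names(group_labels)
  if (is.null(ids)) stop("`group_labels` must be named by sample id")
  clin <- clinical[match(ids, clinical$sample_id), ]
  if (anyNA(clin$sample_id))
    stop("samples missing from clinical table: ",
         paste(head(ids[is.na(clin$sample_id)], 3), collapse = ", "))
  grp <- droplevels(as.factor(group_labels))
  if (nlevels(grp) != 2L) stop("need exactly two non-empty groups")
  events <- tapply(clin$event, grp, sum)
  if (any(events == 0))
    stop("group '", names(events)[events == 0][1L],
         "' has no observed events; the hazard ratio is not estimable")
  fit <- survival::coxph(survival::Surv(clin$time_days, clin$event) ~ grp,
                         ties = "breslow")
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  z <- beta / se
  km <- survival::survfit(survival::Surv(clin$time_days, clin$event) ~ grp)
  tab <- summary(km)$table
  med <- data.frame(group = sub("^grp=", "", rownames(tab)),
                    median = unname(tab[, "median"]),
                    ci_low = unname(tab[, "0.95LCL"]),
                    ci_high = unname(tab[, "0.95UCL"]),
                    stringsAsFactors = FALSE)
  structure(list(group_labels = group_labels,
                 hr = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 median_survival = med,
                 n_per_group = as.vector(table(grp))),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), Wald p = %.3g\n",
              x$hr, x$ci_low, x$ci_high, x$wald_p))
  cat(sprintf("n per group: %s\n", paste(x$n_per_group, collapse = " / ")))
  print(x$median_survival)
  invisible(x)
}

#' Chi-square test of group against tumor stage
#'
#' Builds the group-by-stage contingency table and applies the classical
#' chi-square test of independence without continuity correction.  Stages
#' with zero total count are dropped with a warning; cells with expected
#' count below 5 are flagged.
#'
#' @param group_labels Two-level factor named by sample id.
#' @param stages Character/factor vector of TNM stages, aligned with
#'   `group_labels` (NA stages dropped).
#' @return List with `statistic`, `df`, `p_value`, the observed `table`,
#'   `expected` counts, and `low_expected_cells` (count of cells with
#'   expected < 5).
#' @export
stage_association <- function(group_labels, stages) {
  keep <- !is.na(stages)
  grp <- droplevels(as.factor(group_labels[keep]))
  stg <- as.factor(as.character(stages[keep]))
  tab <- table(grp, stg)
  empty <- colSums(tab) == 0
  if (any(empty)) {
    warning("dropping stage(s) with zero counts: ",
            paste(colnames(tab)[empty], collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("need at least 2 stage categories with counts")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab, expected = ht$expected,
       low_expected_cells = sum(ht$expected < 5))
}
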