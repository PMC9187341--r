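#' Bimodality index of a two-component Gaussian mixture
#'
#' Combines component separation and balance into one score:
#' `BI = sqrt(pi1*pi2) * (mu2 - mu1) / sqrt(pi2*sigma1^2 + pi1*sigma2^2)`.
#' With equal component variances this reduces to the classical
#' `sqrt(pi*(1-pi)) * |mu2 - mu1| / sigma` form.  Higher values indicate two
#' clearly separated, non-trivially occupied modes.
#'
#' @param pi1,pi2 Mixing proportions, both in (0, 1), summing to 1.
#' @param mu1,mu2 Component means with `mu1 <= mu2`.
#' @param sigma1,sigma2 Component standard deviations, strictly positive.
#' @return The bimodality index (non-negative scalar; 0 when `mu1 == mu2`).
#' @export
bimodality_index <- function(pi1, pi2, mu1, mu2, sigma1, sigma2) {
  if (abs(pi1 + pi2 - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (pi1 <= 0 || pi1 >= 1 || pi2 <= 0 || pi2 >= 1)
    stop("mixing proportions must lie strictly in (0, 1)")
  if (mu1 > mu2) stop("components must be ordered: mu1 <= mu2")
  if (sigma1 <= 0 || sigma2 <= 0) stop("standard deviations must be positive")
  if (mu1 == mu2) return(0)
  sqrt(pi1 * pi2) * (mu2 - mu1) / sqrt(pi2 * sigma1^2 + pi1 * sigma2^2)
}

#' Penalize a bimodality index against a control-cohort fit
#'
#' When a feature is two-component in the control cohort as well, its raw
#' tumor bimodality index is penalized by the inverse distance between the
#' tumor and control component parameters:
#' `BI_mu = BI - 1/(|mu1C - mu1T| + |mu2C - mu2T|)` and
#' `BI_pi = BI - 1/(|pi1C - pi1T| + |pi2C - pi2T|)`.
#' The larger of the two penalized values is the final index, clamped at 0.
#' Identical tumor and control parameters (zero distance) are treated as a
#' fully penalized score: the feature is bimodal for reasons present in the
#' healthy population too, and contributes 0.
#'
#' @param bi_raw Unpenalized bimodality index of the tumor fit.
#' @param tumor,control `mixture_fit` objects with `k = 2`, components
#'   ordered by mean.
#' @return List with `bi_mu_penalty`, `bi_pi_penalty` (each `-Inf` when its
#'   distance sum is zero) and `bi_final = max(0, max(both))`.
#' @export
penalized_bi <- function(bi_raw, tumor, control) {
  for (f in list(tumor, control)) {
    if (!inherits(f, "mixture_fit") || f$k != 2L)
      stop("`tumor` and `control` must be two-component mixture_fit objects")
    if (f$mu[1] > f$mu[2]) stop("components must be ordered by mean")
  }
  d_mu <- abs(control$mu[1] - tumor$mu[1]) + abs(control$mu[2] - tumor$mu[2])
  d_pi <- abs(control$pi[1] - tumor$pi[1]) + abs(control$pi[2] - tumor$pi[2])
  bi_mu <- if (d_mu > 0) bi_raw - 1 / d_mu else -Inf
  bi_pi <- if (d_pi > 0) bi_raw - 1 / d_pi else -Inf
  list(bi_mu_penalty = bi_mu, bi_pi_penalty = bi_pi,
       bi_final = max(0, bi_mu, bi_pi))
}

.new_bimodal_call <- function(feature_id, tumor_verdict, control_verdict,
                              bi_raw, bi_mu_penalty, bi_pi_penalty,
                              bi_final, penalized, tumor_fit = NULL,
                              control_fit = NULL) {
  structure(list(feature_id = feature_id, tumor_verdict = tumor_verdict,
                 control_verdict = control_verdict, bi_raw = bi_raw,
                 bi_mu_penalty = bi_mu_penalty,
                 bi_pi_penalty = bi_pi_penalty, bi_final = bi_final,
                 penalized = penalized, tumor_fit = tumor_fit,
                 control_fit = control_fit),
            class = "bimodal_call")
}

.bi_from_fit <- function(fit) {
  bimodality_index(fit$pi[1], fit$pi[2], fit$mu[1], fit$mu[2],
                   fit$sigma[1], fit$sigma[2])
}

# Shared decision tree for one feature.  `control_values = NULL` gives the
# uncontrolled (MM) variant.
.score_one <- function(tumor_values, control_values, seed, bi_source,
                       pi_min, feature_id) {
  tv <- select_model(tumor_values, seed, pi_min = pi_min)
  if (tv$modality != "bimodal")
    return(.new_bimodal_call(feature_id, tv$modality, NA_character_,
                             0, NA_real_, NA_real_, 0, FALSE))
  tumor_km <- kmeans_recluster(tumor_values)
  tumor_par <- if (bi_source == "kmeans") tumor_km else tv$fit2
  bi_raw <- .bi_from_fit(tumor_par)
  if (is.null(control_values))
    return(.new_bimodal_call(feature_id, "bimodal", NA_character_,
                             bi_raw, NA_real_, NA_real_, bi_raw, FALSE,
                             tumor_par))
  cv <- select_model(control_values, seed, pi_min = pi_min)
  if (cv$modality != "bimodal")
    return(.new_bimodal_call(feature_id, "bimodal", cv$modality,
                             bi_raw, NA_real_, NA_real_, bi_raw, FALSE,
                             tumor_par))
  control_km <- kmeans_recluster(control_values)
  control_par <- if (bi_source == "kmeans") control_km else cv$fit2
  pen <- penalized_bi(bi_raw, tumor_par, control_par)
  .new_bimodal_call(feature_id, "bimodal", "bimodal", bi_raw,
                    pen$bi_mu_penalty, pen$bi_pi_penalty, pen$bi_final,
                    TRUE, tumor_par, control_par)
}

#' Controlled mixture-model score for one feature
#'
#' Full decision tree of the controlled method (CM): select the tumor model
#' by BIC with the mixing-proportion constraint; unimodal or
#' outlier-excluded features score 0.  Otherwise re-cluster the tumor values
#' with k-means, compute the raw bimodality index, and fit the control
#' cohort: a unimodal control leaves the index unpenalized, a bimodal
#' control triggers the inverse-distance penalties of [penalized_bi()].
#'
#' @param tumor_values,control_values Log2-scale expression vectors for one
#'   feature in each cohort.
#' @param seed Passed through to the (deterministic) fitters.
#' @param bi_source Take component parameters for the index from the k-means
#'   re-clustering (default) or from the EM fit.
#' @param pi_min Mixing-proportion constraint for a bimodal verdict.
#' @return A `bimodal_call`.
#' @export
cm_score <- function(tumor_values, control_values, seed = NULL,
                     bi_source = c("kmeans", "em"), pi_min = 0.1) {
  bi_source <- match.arg(bi_source)
  .score_one(tumor_values, control_values, seed, bi_source, pi_min, NA)
}

#' Uncontrolled mixture-model score for one feature
#'
#' The same pipeline as [cm_score()] with no control branch: mixture model,
#' BIC selection, k-means re-clustering and the unpenalized bimodality
#' index.
#'
#' @inheritParams cm_score
#' @return A `bimodal_call` with `penalized = FALSE`.
#' @export
mm_score <- function(tumor_values, seed = NULL,
                     bi_source = c("kmeans", "em"), pi_min = 0.1) {
  bi_source <- match.arg(bi_source)
  .score_one(tumor_values, NULL, seed, bi_source, pi_min, NA)
}

#' Score every feature of a tumor (and optionally control) cohort
#'
#' Applies [cm_score()] (`mode = "cm"`, control required) or [mm_score()]
#' (`mode = "mm"`) to each feature and collects one row per input feature.
#'
#' @param tumor An [expression_matrix()] on the log2 scale.
#' @param control Optional control [expression_matrix()] with the same
#'   features (required for `mode = "cm"`).
#' @param mode `"cm"` or `"mm"`.
#' @inheritParams cm_score
#' @return A data.frame with columns `feature_id`, `tumor_verdict`,
#'   `control_verdict`, fitted tumor parameters, `bi_raw`, both penalties,
#'   `bi_final` and `penalized`.
#' @export
detect_bimodal <- function(tumor, control = NULL, mode = c("cm", "mm"),
                           seed = NULL, bi_source = c("kmeans", "em"),
                           pi_min = 0.1) {
  mode <- match.arg(mode)
  bi_source <- match.arg(bi_source)
  stopifnot(inherits(tumor, "expression_matrix"))
  if (tumor$scale != "log2")
    stop("detection expects log2-scale expression; run log2_transform() first")
  if (mode == "cm") {
    if (is.null(control)) stop("`mode = \"cm\"` requires a control matrix")
    stopifnot(inherits(control, "expression_matrix"))
    if (control$scale != "log2")
      stop("control matrix must be on the log2 scale")
    missing <- setdiff(rownames(tumor$values), rownames(control$values))
    if (length(missing))
      stop("features absent from control cohort: ",
           paste(head(missing, 3), collapse = ", "))
  }
  ids <- rownames(tumor$values)
  if (length(ids) == 0L)
    return(data.frame(feature_id = character(0),
                      tumor_verdict = character(0),
                      control_verdict = character(0),
                      mu1 = numeric(0), mu2 = numeric(0),
                      sigma1 = numeric(0), sigma2 = numeric(0),
                      pi1 = numeric(0), pi2 = numeric(0),
                      bi_raw = numeric(0), bi_mu_penalty = numeric(0),
                      bi_pi_penalty = numeric(0), bi_final = numeric(0),
                      penalized = logical(0), stringsAsFactors = FALSE))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    call <- if (mode == "cm")
      cm_score(tumor$values[i, ], control$values[ids[i], ], seed,
               bi_source, pi_min)
    else
      mm_score(tumor$values[i, ], seed, bi_source, pi_min)
    tf <- call$tumor_fit
    rows[[i]] <- data.frame(
      feature_id = ids[i],
      tumor_verdict = call$tumor_verdict,
      control_verdict = call$control_verdict,
      mu1 = if (is.null(tf)) NA_real_ else tf$mu[1],
      mu2 = if (is.null(tf)) NA_real_ else tf$mu[2],
      sigma1 = if (is.null(tf)) NA_real_ else tf$sigma[1],
      sigma2 = if (is.null(tf)) NA_real_ else tf$sigma[2],
      pi1 = if (is.null(tf)) NA_real_ else tf$pi[1],
      pi2 = if (is.null(tf)) NA_real_ else tf$pi[2],
      bi_raw = call$bi_raw,
      bi_mu_penalty = call$bi_mu_penalty,
      bi_pi_penalty = call$bi_pi_penalty,
      bi_final = call$bi_final,
      penalized = call$penalized,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank scored features by final bimodality index
#'
#' Sorts descending by `bi_final` with ties broken by feature id, and
#' reports feature counts above the conventional index thresholds
#' 0, 1, 1.2, 1.3, 1.4 and 1.5.
#'
#' @param calls Data.frame from [detect_bimodal()] (needs `feature_id` and
#'   `bi_final`).
#' @param bi_threshold Threshold used for the `above_threshold` flag column.
#' @return The ranked data.frame with a `rank` column and an attribute
#'   `threshold_counts` (named vector of counts with `bi_final` strictly
#'   above each threshold).
#' @export
rank_features <- function(calls, bi_threshold = 1.4) {
  thresholds <- c(0, 1, 1.2, 1.3, 1.4, 1.5)
  if (nrow(calls) == 0L) {
    out <- cbind(calls, rank = integer(0), above_threshold = logical(0))
    attr(out, "threshold_counts") <-
      setNames(rep(0L, length(thresholds)), paste0("BI>", thresholds))
    return(out)
  }
  ord <- order(-calls$bi_final, calls$feature_id)
  out <- calls[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$above_threshold <- out$bi_final > bi_threshold
  rownames(out) <- NULL
  attr(out, "threshold_counts") <- setNames(
    vapply(thresholds, function(t) sum(calls$bi_final > t), integer(1)),
    paste0("BI>", thresholds))
  out
}

#' False-positive-rate simulation for the bimodality pipeline
#'
#' Draws `n_features` independent unimodal Gaussian features of length
#' `n_samples` (and, in CM mode, matching unimodal control features), runs
#' the full scoring pipeline on each, and returns the fraction whose final
#' bimodality index exceeds `bi_threshold` — an estimate of the false
#' positive rate of the detector at that sample size and threshold.
#'
#' @param n_samples Samples per simulated feature.
#' @param n_features Number of simulated null features (use 1000+ for a
#'   stable estimate).
#' @param bi_threshold Index threshold defining a (false) positive.
#' @param seed Integer seed for the simulated data.
#' @param pipeline `"mm"` (tumor only) or `"cm"` (with unimodal controls).
#' @param mu,sigma Mean and standard deviation of the null Gaussian
#'   features, on the log2-expression scale.
#' @return Fraction of features with `bi_final > bi_threshold`.
#' @export
simulate_fpr <- function(n_samples, n_features, bi_threshold = 1.4, seed = 1,
                         pipeline = c("mm", "cm"), mu = 5, sigma = 1) {
  pipeline <- match.arg(pipeline)
  if (n_features < 1L) stop("`n_features` must be positive")
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_features)) {
    x <- rnorm(n_samples, mu, sigma)
    call <- if (pipeline == "cm")
      cm_score(x, rnorm(n_samples, mu, sigma))
    else
      mm_score(x)
    if (call$bi_final > bi_threshold) hits <- hits + 1L
  }
  hits / n_features
}
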