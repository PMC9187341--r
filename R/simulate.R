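#' Specify one synthetic feature
#'
#' Describes the generative law of a single feature on the log2-expression
#' scale.  Archetypes: `unimodal` (one Gaussian in both cohorts),
#' `tumor_bimodal` (two components in tumor, one in control),
#' `shared_bimodal` (the same two components in both cohorts) and
#' `low_expressed` (zero in most samples, to exercise the low-expression
#' filter).
#'
#' @param feature_id Feature name.
#' @param archetype One of `unimodal`, `tumor_bimodal`, `shared_bimodal`,
#'   `low_expressed`.
#' @param mu1,mu2 Component means (log2 scale), `mu1 <= mu2`; a unimodal
#'   feature must have `mu1 == mu2`.
#' @param sigma1,sigma2 Component standard deviations, positive.
#' @param pi1 Mixing proportion of the lower component in tumor, in (0, 1).
#' @param control_params Optional list overriding `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `pi1` for the control cohort.  Default control behavior:
#'   `tumor_bimodal` controls are drawn from the lower component only;
#'   `shared_bimodal` controls reuse the tumor mixture.
#' @param linked If `TRUE`, tumor component membership follows the cohort's
#'   shared latent subgroup (producing concurrently expressed features and a
#'   survival-relevant split) instead of independent per-sample draws.
#' @param zero_frac For `low_expressed`: fraction of exact zeros (>= 0.95).
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(feature_id,
                         archetype = c("unimodal", "tumor_bimodal",
                                       "shared_bimodal", "low_expressed"),
                         mu1, mu2 = mu1, sigma1 = 1, sigma2 = sigma1,
                         pi1 = 0.5, control_params = NULL, linked = FALSE,
                         zero_frac = 0.97) {
  archetype <- match.arg(archetype)
  if (pi1 <= 0 || pi1 >= 1) stop("`pi1` must lie strictly in (0, 1)")
  if (mu1 > mu2) stop("`mu1` must not exceed `mu2`")
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigmas must be positive")
  if (archetype == "unimodal" && mu1 != mu2)
    stop("a unimodal feature must have mu1 == mu2")
  if (archetype == "low_expressed" && zero_frac < 0.95)
    stop("`zero_frac` must be at least 0.95 for low_expressed features")
  structure(list(feature_id = feature_id, archetype = archetype,
                 mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                 pi1 = pi1, control_params = control_params,
                 linked = linked, zero_frac = zero_frac),
            class = "feature_spec")
}

#' Configure a synthetic cohort
#'
#' Bundles the study-design parameters of a simulated tumor/control study:
#' cohort sizes (control no larger than tumor, as in real tumor registries),
#' the feature generative laws, the survival hazard multiplier for the
#' high-expression subgroup, the censoring fraction, and an optional drug
#' panel with target expression-log(IC50) correlations.
#'
#' @param n_tumor,n_control Sample counts (`n_control <= n_tumor`).
#' @param feature_specs List of [feature_spec()] objects.
#' @param hazard_ratio Hazard multiplier for membership in the
#'   high-expression subgroup (must be positive).
#' @param censor_rate Expected fraction of censored samples, in `[0, 1)`.
#' @param drug_panel Optional data.frame/list of `drug_id`, `target_corr`
#'   pairs with `|target_corr| <= 1`.
#' @param seed Integer seed; fully determines every generated output.
#' @param subgroup_prob Probability that a tumor sample belongs to the
#'   high-expression latent subgroup driving linked features and survival.
#' @param stage_probs Categorical distribution of TNM stages I-IV.
#' @param stage_shift Log-odds tilt of the high subgroup toward later
#'   stages (0 = stage independent of expression).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_tumor, n_control, feature_specs,
                          hazard_ratio = 1, censor_rate = 0,
                          drug_panel = NULL, seed = 1,
                          subgroup_prob = 0.5,
                          stage_probs = c(I = 0.30, II = 0.30,
                                          III = 0.25, IV = 0.15),
                          stage_shift = 0) {
  if (n_control > n_tumor)
    stop("`n_control` must not exceed `n_tumor`")
  if (!all(vapply(feature_specs, inherits, logical(1), "feature_spec")))
    stop("`feature_specs` must be a list of feature_spec objects")
  ids <- vapply(feature_specs, `[[`, character(1), "feature_id")
  if (anyDuplicated(ids)) stop("duplicate feature ids in specs")
  if (hazard_ratio <= 0) stop("`hazard_ratio` must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("`censor_rate` must be in [0, 1)")
  if (!is.null(drug_panel)) {
    drug_panel <- as.data.frame(drug_panel)
    if (!all(c("drug_id", "target_corr") %in% names(drug_panel)))
      stop("`drug_panel` needs columns drug_id and target_corr")
    if (any(abs(drug_panel$target_corr) > 1))
      stop("|target_corr| must not exceed 1")
  }
  if (abs(sum(stage_probs) - 1) > 1e-8) stop("`stage_probs` must sum to 1")
  structure(list(n_tumor = as.integer(n_tumor),
                 n_control = as.integer(n_control),
                 feature_specs = feature_specs,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate,
                 drug_panel = drug_panel, seed = as.integer(seed),
                 subgroup_prob = subgroup_prob, stage_probs = stage_probs,
                 stage_shift = stage_shift),
            class = "cohort_config")
}

.draw_feature <- function(spec, n, membership) {
  mu <- c(spec$mu1, spec$mu2)
  sg <- c(spec$sigma1, spec$sigma2)
  rnorm(n, mu[membership], sg[membership])
}

.control_spec <- function(spec) {
  cp <- spec$control_params
  out <- spec[c("mu1", "mu2", "sigma1", "sigma2", "pi1")]
  if (!is.null(cp)) out[names(cp)] <- cp
  out
}

#' Generate a tumor/control cohort with known ground truth
#'
#' Draws log2-scale expression for every configured feature in both
#' cohorts.  Tumor membership in the two components of a bimodal feature is
#' either an independent Bernoulli(`1 - pi1`) draw per sample or, for
#' `linked` features, the cohort's shared latent subgroup (so linked
#' features are concurrently expressed).  Control draws follow the
#' archetype: single lower component for `tumor_bimodal`, the same mixture
#' for `shared_bimodal`.  Values are truncated at 0 (log2 of the smallest
#' expressible raw value) so the raw-scale export `2^x - 1` is valid.
#'
#' @param config A [cohort_config()].
#' @return List with `tumor` and `control` [expression_matrix()] objects
#'   (log2 scale) and `truth`: per-feature archetypes, the per-sample
#'   latent `subgroup` (`"low"`/`"high"`), and per-feature tumor/control
#'   component `membership` matrices (1 = lower, 2 = upper, NA for
#'   single-component draws).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  nT <- config$n_tumor
  nC <- config$n_control
  tumor_ids <- sprintf("T%04d", seq_len(nT))
  control_ids <- sprintf("C%04d", seq_len(nC))
  specs <- config$feature_specs
  fids <- vapply(specs, `[[`, character(1), "feature_id")

  subgroup <- ifelse(runif(nT) < config$subgroup_prob, 2L, 1L)
  names(subgroup) <- tumor_ids

  tumor <- matrix(NA_real_, length(specs), nT,
                  dimnames = list(fids, tumor_ids))
  control <- matrix(NA_real_, length(specs), nC,
                    dimnames = list(fids, control_ids))
  memT <- matrix(NA_integer_, length(specs), nT,
                 dimnames = list(fids, tumor_ids))
  memC <- matrix(NA_integer_, length(specs), nC,
                 dimnames = list(fids, control_ids))

  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    cs <- .control_spec(sp)
    if (sp$archetype == "unimodal") {
      tumor[i, ] <- rnorm(nT, sp$mu1, sp$sigma1)
      control[i, ] <- rnorm(nC, cs$mu1, cs$sigma1)
    } else if (sp$archetype == "low_expressed") {
      zT <- runif(nT) < sp$zero_frac
      zC <- runif(nC) < sp$zero_frac
      tumor[i, ] <- ifelse(zT, 0, rnorm(nT, sp$mu1, sp$sigma1))
      control[i, ] <- ifelse(zC, 0, rnorm(nC, cs$mu1, cs$sigma1))
    } else {
      mT <- if (sp$linked) subgroup
            else ifelse(runif(nT) < sp$pi1, 1L, 2L)
      tumor[i, ] <- .draw_feature(sp, nT, mT)
      memT[i, ] <- mT
      if (sp$archetype == "shared_bimodal") {
        mC <- ifelse(runif(nC) < cs$pi1, 1L, 2L)
        control[i, ] <- rnorm(nC, c(cs$mu1, cs$mu2)[mC],
                              c(cs$sigma1, cs$sigma2)[mC])
        memC[i, ] <- mC
      } else {
        control[i, ] <- rnorm(nC, cs$mu1, cs$sigma1)
      }
    }
  }
  tumor[tumor < 0] <- 0       # floor of the log2(x+1) scale
  control[control < 0] <- 0

  truth <- list(
    features = data.frame(
      feature_id = fids,
      archetype = vapply(specs, `[[`, character(1), "archetype"),
      linked = vapply(specs, `[[`, logical(1), "linked"),
      stringsAsFactors = FALSE),
    subgroup = factor(ifelse(subgroup == 2L, "high", "low"),
                      levels = c("low", "high")),
    membership_tumor = memT,
    membership_control = memC)
  names(truth$subgroup) <- tumor_ids

  list(tumor = expression_matrix(tumor, "tumor", "log2"),
       control = expression_matrix(control, "control", "log2"),
       truth = truth)
}

#' Convert a log2-scale matrix to the raw scale
#'
#' Applies `2^x - 1`, the inverse of the default [log2_transform()], so the
#' preprocessing round-trips on exported synthetic data.
#'
#' @param m An [expression_matrix()] with `scale = "log2"`.
#' @export
as_raw_scale <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2") stop("matrix is not on the log2 scale")
  m$values <- 2^m$values - 1
  m$values[m$values < 0] <- 0   # guard float round-off near zero
  m$scale <- "raw"
  m
}

#' Generate a clinical table matched to the simulated tumor cohort
#'
#' Survival times are exponential: baseline hazard `log(2)/730` per day
#' (two-year median survival) multiplied by `config$hazard_ratio` for
#' samples in the high-expression subgroup, so the configured multiplier is
#' exactly the true hazard ratio.  Censoring is independent exponential
#' with its rate chosen to censor approximately `censor_rate` of samples.
#' TNM stages are drawn from `config$stage_probs`, independent of
#' expression unless `stage_shift` tilts the high subgroup toward later
#' stages.
#'
#' @param truth Ground-truth list from [generate_cohort()] (uses
#'   `subgroup`).
#' @param config The same [cohort_config()].
#' @return Data.frame with `sample_id`, `time_days`, `event` (1 = death),
#'   `stage` (I-IV), `sex`.
#' @export
generate_clinical <- function(truth, config) {
  stopifnot(inherits(config, "cohort_config"))
  subgroup <- truth$subgroup
  n <- length(subgroup)
  if (n != config$n_tumor)
    stop("truth subgroup does not cover the tumor cohort")
  set.seed(config$seed + 1L)
  base_hazard <- log(2) / 730
  rate <- base_hazard * ifelse(subgroup == "high", config$hazard_ratio, 1)
  t_event <- rexp(n, rate)
  if (config$censor_rate > 0) {
    c_rate <- config$censor_rate / (1 - config$censor_rate) * mean(rate)
    t_cens <- rexp(n, c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  stages <- names(config$stage_probs)
  stage <- character(n)
  w_low <- config$stage_probs
  w_high <- config$stage_probs * exp(config$stage_shift *
                                     (seq_along(stages) - 1))
  w_high <- w_high / sum(w_high)
  is_high <- subgroup == "high"
  stage[!is_high] <- sample(stages, sum(!is_high), TRUE, prob = w_low)
  stage[is_high] <- sample(stages, sum(is_high), TRUE, prob = w_high)
  data.frame(sample_id = names(subgroup), time_days = time, event = event,
             stage = stage, sex = sample(c("F", "M"), n, TRUE),
             stringsAsFactors = FALSE)
}

#' Generate a cell-line expression/IC50 panel with planted correlations
#'
#' Draws one expression value per cell line and, for each configured drug,
#' a log(IC50) constructed as `rho * z(expr) + sqrt(1 - rho^2) * noise`, so
#' the population correlation with expression is exactly the drug's
#' `target_corr` (and the empirical correlation is exact when
#' `|target_corr| = 1`).  IC50 values are exported in micromolar as
#' `exp(log_ic50)`.
#'
#' @param config A [cohort_config()] with a non-empty `drug_panel`.
#' @param n_cell_lines Number of cell lines (at least 3; default 13,
#'   a typical small screening panel).
#' @return List with `expression` (named vector) and `ic50` (cell line by
#'   drug matrix, micromolar).
#' @export
generate_drug_panel <- function(config, n_cell_lines = 13) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$drug_panel) || nrow(config$drug_panel) == 0L)
    stop("config has no drug panel")
  if (n_cell_lines < 3L) stop("`n_cell_lines` must be at least 3")
  set.seed(config$seed + 2L)
  lines <- sprintf("CL%02d", seq_len(n_cell_lines))
  expr <- setNames(rnorm(n_cell_lines, 5, 1.5), lines)
  z <- as.vector(scale(expr))
  ic50 <- matrix(NA_real_, n_cell_lines, nrow(config$drug_panel),
                 dimnames = list(lines, config$drug_panel$drug_id))
  for (j in seq_len(nrow(config$drug_panel))) {
    rho <- config$drug_panel$target_corr[j]
    noise <- rnorm(n_cell_lines)
    ic50[, j] <- exp(rho * z + sqrt(1 - rho^2) * noise)
  }
  list(expression = expr, ic50 = ic50)
}

#' Write a synthetic study bundle to disk
#'
#' Exports tumor and control expression as raw-scale TSV (round-tripping
#' through [log2_transform()]), the clinical table as TSV, the IC50 panel
#' as CSV, and a ground-truth JSON sidecar.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param n_cell_lines Cell lines for the drug panel (if configured).
#' @return Invisibly, the list of written paths.
#' @export
write_cohort_bundle <- function(config, dir, n_cell_lines = 13) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(config)
  clinical <- generate_clinical(sim$truth, config)
  paths <- list(tumor = file.path(dir, "tumor.tsv"),
                control = file.path(dir, "control.tsv"),
                clinical = file.path(dir, "clinical.tsv"),
                truth = file.path(dir, "truth.json"))
  write_expression_tsv(as_raw_scale(sim$tumor), paths$tumor)
  write_expression_tsv(as_raw_scale(sim$control), paths$control)
  write.table(clinical, paths$clinical, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(config$drug_panel) && nrow(config$drug_panel)) {
    panel <- generate_drug_panel(config, n_cell_lines)
    paths$ic50 <- file.path(dir, "ic50.csv")
    paths$cellline_expr <- file.path(dir, "cellline_expression.tsv")
    write.csv(data.frame(cell_line = rownames(panel$ic50), panel$ic50,
                         check.names = FALSE),
              paths$ic50, row.names = FALSE, quote = FALSE)
    write.table(data.frame(cell_line = names(panel$expression),
                           expression = panel$expression),
                paths$cellline_expr, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  truth_json <- list(
    features = sim$truth$features,
    subgroup = as.list(setNames(as.character(sim$truth$subgroup),
                                names(sim$truth$subgroup))),
    seed = config$seed)
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
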