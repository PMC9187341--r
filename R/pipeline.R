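#' Run the full detection workflow on files
#'
#' End-to-end orchestration: read tumor (and control) expression TSVs,
#' filter lowly expressed features on the tumor cohort (the same feature
#' list is applied to control), log2-transform, optionally bootstrap the
#' tumor cohort down to the control size, score every feature (CM or MM),
#' rank, detect co-expression modules among features above the index
#' threshold, and — when a clinical table is supplied — stratify patients by
#' each module (and by all module features jointly) and fit the
#' proportional-hazards comparison.  When an IC50 table and cell-line
#' expression file are supplied, drugs are ranked by expression-log(IC50)
#' correlation.  All outputs are plain TSV/JSON under `out_dir`, plus a
#' manifest recording parameters, seed and per-stage row counts; identical
#' inputs, parameters and seed give identical outputs.
#'
#' @param tumor_path Tumor expression TSV (raw scale).
#' @param control_path Control expression TSV (required for `mode = "cm"`).
#' @param clinical_path Optional clinical TSV (`sample_id`, `time_days`,
#'   `event`, `stage`, `sex`).
#' @param ic50_path,cellline_expr_path Optional drug-response inputs: IC50
#'   CSV (cell line by drug) and a two-column cell-line expression TSV.
#' @param out_dir Output directory.
#' @param mode `"cm"` or `"mm"`.
#' @param seed Integer seed recorded in the manifest and used for any
#'   resampling.
#' @param pseudocount,min_nonzero_frac,min_mean_raw Preprocessing knobs.
#' @param bootstrap_to_control If `TRUE`, bootstrap the tumor cohort to the
#'   control cohort's size before scoring.
#' @param pi_min,bi_source,bi_threshold Detection knobs (see
#'   [detect_bimodal()]).
#' @param r_threshold,min_module_size Module criteria.
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(tumor_path, control_path = NULL,
                         clinical_path = NULL, ic50_path = NULL,
                         cellline_expr_path = NULL, out_dir,
                         mode = c("cm", "mm"), seed = 1,
                         pseudocount = 1, min_nonzero_frac = 0.1,
                         min_mean_raw = 1, bootstrap_to_control = FALSE,
                         pi_min = 0.1, bi_source = "kmeans",
                         bi_threshold = 1.4, r_threshold = 0.5,
                         min_module_size = 3) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bimodalCM")),
    mode = mode, seed = seed,
    parameters = list(pseudocount = pseudocount,
                      min_nonzero_frac = min_nonzero_frac,
                      min_mean_raw = min_mean_raw,
                      bootstrap_to_control = bootstrap_to_control,
                      pi_min = pi_min, bi_source = bi_source,
                      bi_threshold = bi_threshold,
                      r_threshold = r_threshold,
                      min_module_size = min_module_size),
    stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message("[", stage, "] ", paste(names(list(...)), unlist(list(...)),
                                    sep = "=", collapse = " "))
  }

  # --- preprocess -----------------------------------------------------
  tumor_raw <- read_expression_tsv(tumor_path, "tumor")
  filt <- filter_low_expressed(tumor_raw, min_nonzero_frac, min_mean_raw)
  tumor <- log2_transform(filt$matrix, pseudocount)
  control <- NULL
  if (mode == "cm") {
    if (is.null(control_path))
      stop("stage preprocess: mode \"cm\" requires `control_path`")
    control_raw <- read_expression_tsv(control_path, "control")
    control <- log2_transform(
      subset_features(control_raw, rownames(tumor$values)), pseudocount)
  }
  note("preprocess", features_in = nrow(tumor_raw$values),
       features_kept = nrow(tumor$values),
       removed = length(filt$removed_ids))

  # --- optional bootstrap size matching -------------------------------
  if (bootstrap_to_control) {
    if (is.null(control)) stop("stage bootstrap: no control cohort to match")
    tumor <- bootstrap_match(tumor, ncol(control$values), seed)
    note("bootstrap", tumor_n = ncol(tumor$values))
  }

  # --- detect ---------------------------------------------------------
  calls <- detect_bimodal(tumor, control, mode, seed, bi_source, pi_min)
  ranked <- rank_features(calls, bi_threshold)
  write.table(ranked, file.path(out_dir, "bimodal_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- attr(ranked, "threshold_counts")
  note("detect", features = nrow(ranked),
       above_threshold = sum(ranked$above_threshold))

  # --- modules --------------------------------------------------------
  hits <- ranked$feature_id[ranked$above_threshold]
  modules <- list()
  if (length(hits) >= min_module_size) {
    corr <- pairwise_correlations(tumor, hits)
    modules <- find_modules(corr, r_threshold, min_module_size)
  }
  mod_df <- if (length(modules)) data.frame(
    module_id = sprintf("M%02d", seq_along(modules)),
    size = vapply(modules, function(m) length(m$features), integer(1)),
    min_pairwise_r = vapply(modules, `[[`, numeric(1), "min_pairwise_r"),
    features = vapply(modules, function(m)
      paste(m$features, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  else data.frame(module_id = character(0), size = integer(0),
                  min_pairwise_r = numeric(0), features = character(0))
  write.table(mod_df, file.path(out_dir, "modules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("modules", n_modules = length(modules))

  # --- survival -------------------------------------------------------
  surv_results <- NULL
  if (!is.null(clinical_path)) {
    if (!file.exists(clinical_path))
      stop("stage survival: clinical file not found: ", clinical_path)
    clinical <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
    surv_results <- list()
    if (length(modules)) {
      all_feats <- unique(unlist(lapply(modules, `[[`, "features")))
      targets <- c(list(all_modules = all_feats),
                   setNames(lapply(modules, `[[`, "features"),
                            mod_df$module_id))
      for (nm in names(targets)) {
        labels <- stratify_hierarchical(tumor, targets[[nm]])
        res <- tryCatch(fit_cox(labels, clinical), error = function(e) e)
        if (inherits(res, "error")) {
          warning("stage survival (", nm, "): ", conditionMessage(res))
          next
        }
        stg <- stage_association(
          labels, clinical$stage[match(names(labels), clinical$sample_id)])
        surv_results[[nm]] <- list(
          hr = res$hr, ci_low = res$ci_low, ci_high = res$ci_high,
          wald_p = res$wald_p, n_per_group = res$n_per_group,
          median_survival = res$median_survival,
          stage_chisq = stg$statistic, stage_p = stg$p_value)
        write.table(data.frame(sample_id = names(labels),
                               group = as.character(labels)),
                    file.path(out_dir, paste0("stratification_", nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      jsonlite::write_json(surv_results,
                           file.path(out_dir, "survival.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    note("survival", n_stratifications = length(surv_results))
  }

  # --- drug response --------------------------------------------------
  drug_results <- NULL
  if (!is.null(ic50_path)) {
    if (is.null(cellline_expr_path))
      stop("stage drugcorr: `cellline_expr_path` is required with an IC50 table")
    ic50 <- utils::read.csv(ic50_path, row.names = 1, check.names = FALSE)
    ce <- utils::read.delim(cellline_expr_path, stringsAsFactors = FALSE)
    expr <- setNames(ce[[2L]], ce[[1L]])
    corrs <- correlate_drugs(expr, ic50)
    drug_results <- rank_drugs(corrs)
    write.table(corrs[order(corrs$r, corrs$drug_id), ],
                file.path(out_dir, "drug_correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("drugcorr", n_drugs = nrow(corrs))
  }

  manifest$threshold_counts <- as.list(counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(calls = ranked, modules = modules,
                 survival = surv_results, drugs = drug_results,
                 manifest = manifest))
}
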