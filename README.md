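# bimodalCM

Controlled mixture modeling (CM) for detecting **bimodally expressed
features** in tumor cohorts. Tumor heterogeneity means many oncogenic
miRNAs and genes are highly expressed only in a subset of patients:
their expression distribution has two modes, which mean-difference tests
against controls cannot see. CM scores each feature by how clearly
two-moded it is in tumors and *penalizes* the score when the matched
control cohort shows a similar two-component structure, suppressing
features (immunoglobulins, copy-number variants, ...) that are bimodal in
healthy tissue too. The package is aimed at analysts of bulk miRNA-seq /
RNA-seq tumor cohorts with matched normals, and ships everything needed
to exercise the method end to end on synthetic cohorts with known ground
truth.

## The method

Per feature (log2 scale), one- and two-component Gaussian models are fit
by EM; BIC ($-2\ell + p\log n$) picks the winner and two-component
winners need both mixing proportions $> 0.1$. Surviving features are
re-clustered with exact 1-D $k$-means ($k=2$) and ranked by the
bimodality index

$$\mathrm{BI} = \sqrt{\pi_1\pi_2}\,\frac{\mu_2-\mu_1}
{\sqrt{\pi_2\sigma_1^2+\pi_1\sigma_2^2}}.$$

If the control cohort is also two-component, the index is penalized by
the inverse parameter distance between cohorts,

$$\mathrm{BI}_\mu = \mathrm{BI} - \tfrac{1}{|\mu_{1C}-\mu_{1T}|+|\mu_{2C}-\mu_{2T}|},
\qquad
\mathrm{BI}_\pi = \mathrm{BI} - \tfrac{1}{|\pi_{1C}-\pi_{1T}|+|\pi_{2C}-\pi_{2T}|},$$

and the larger of the two (clamped at 0) is the final index. Downstream:
features above threshold (default 1.4) are grouped into **concurrent
expression modules** (maximal cliques with all pairwise Pearson
$r > 0.5$, size $\ge 3$), modules stratify patients (Manhattan /
complete-linkage clustering cut at 2) for **Cox proportional-hazards**
survival comparison, and per-cell-line expression is correlated with drug
**log(IC50)** to rank candidate compounds. See the vignette
(`vignettes/controlled-mixture-modeling.Rmd`) for assumptions, numerical
choices and limitations.

## Worked example

```r
library(bimodalCM)

specs <- c(
  lapply(1:20, function(i) feature_spec(sprintf("uni%02d", i), "unimodal", mu1 = 5)),
  lapply(1:3,  function(i) feature_spec(sprintf("miR.mod%d", i), "tumor_bimodal",
                                        mu1 = 2, mu2 = 8, linked = TRUE)),
  list(feature_spec("miR.shared", "shared_bimodal", mu1 = 2, mu2 = 8)))
cfg <- cohort_config(n_tumor = 200, n_control = 60, specs,
                     hazard_ratio = 2.5, censor_rate = 0.2, seed = 42)
sim <- generate_cohort(cfg)

calls <- rank_features(detect_bimodal(sim$tumor, sim$control, mode = "cm"))
head(calls[, c("feature_id", "tumor_verdict", "bi_raw", "bi_final", "penalized")], 5)
#>   feature_id tumor_verdict bi_raw bi_final penalized
#> 1   miR.mod2       bimodal   2.93     2.93     FALSE
#> 2   miR.mod1       bimodal   2.91     2.91     FALSE
#> 3   miR.mod3       bimodal   2.71     2.71     FALSE
#> 4 miR.shared       bimodal   2.96     0.00      TRUE
#> 5      uni01      unimodal   0.00     0.00     FALSE
```

The three planted tumor-specific features are called with index ≈ 2.9;
the feature that is equally bimodal in controls has raw index 2.96 but is
penalized to 0; unimodal background scores 0. The hits form one module
and stratify patients into groups whose hazard ratio recovers the planted
risk (true value 2.5):

```r
hits <- calls$feature_id[calls$above_threshold]
mods <- find_modules(pairwise_correlations(sim$tumor, hits))
mods[[1]]$features
#> [1] "miR.mod1" "miR.mod2" "miR.mod3"

labels <- stratify_hierarchical(sim$tumor, mods[[1]]$features)
fit_cox(labels, generate_clinical(sim$truth, cfg))
#> HR 2.208 (95% CI 1.591-3.063), Wald p = 2.14e-06
#> n per group: 111 / 89
#>   group   median   ci_low  ci_high
#> 1   low 606.8507 429.1974 915.1246
#> 2  high 314.2166 211.5732 446.3243
```

High-expressing patients die roughly twice as fast (median survival 314
vs 607 days). `run_pipeline()` chains the same stages over TSV/CSV files
and writes TSV/JSON outputs plus a manifest; `inst/cli/bimodalcm` is a
thin shell wrapper (`simulate`, `detect`, `fpr`, `run`).

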