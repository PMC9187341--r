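# Shared fixtures and independent oracles, built in code at test time.

# A batch of identical feature specs with numbered ids.
spec_batch <- function(n, prefix, ...) {
  lapply(seq_len(n), function(i)
    feature_spec(sprintf("%s%03d", prefix, i), ...))
}

# The mixed cohort used for discrimination checks: 50 unimodal,
# 25 tumor-only bimodal and 25 shared-bimodal features, components
# separated by six standard deviations with balanced proportions.
discrimination_specs <- function() {
  c(spec_batch(50, "uni", archetype = "unimodal", mu1 = 5),
    spec_batch(25, "tb", archetype = "tumor_bimodal", mu1 = 2, mu2 = 8),
    spec_batch(25, "sb", archetype = "shared_bimodal", mu1 = 2, mu2 = 8))
}

# Small expression_matrix from a plain matrix, inventing dimnames.
as_em <- function(vals, cohort = "tumor", scale = "log2") {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("f%03d", seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("s%03d", seq_len(ncol(vals)))
  expression_matrix(vals, cohort, scale)
}

# Fabricate a two-component mixture_fit with given parameters (for tests
# of the penalty arithmetic, which only reads mu and pi).
fake_fit2 <- function(mu, sigma = c(1, 1), pi = c(0.5, 0.5)) {
  structure(list(k = 2L, mu = mu, sigma = sigma, pi = pi,
                 loglik = NA_real_, bic = NA_real_,
                 assignments = integer(0), method = "em", n = 0L),
            class = "mixture_fit")
}

# Independent oracle: minimum within-cluster SSE over every contiguous
# split of the sorted vector (optimal 1-D 2-means is such a split).
brute_force_best_sse <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (j in seq_len(n - 1L)) {
    lo <- xs[seq_len(j)]
    hi <- xs[(j + 1L):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best) best <- sse
  }
  best
}

partition_sse <- function(x, assignments) {
  sum(vapply(split(x, assignments), function(v)
    sum((v - mean(v))^2), numeric(1)))
}

# Independent oracle: all maximal subsets of size >= min_size whose
# pairwise correlations all exceed r_threshold, by exhaustive enumeration.
brute_force_modules <- function(corr, r_threshold = 0.5, min_size = 3) {
  n <- nrow(corr)
  ids <- rownames(corr)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  qualifying <- list()
  for (size in min_size:n) {
    for (comb in utils::combn(n, size, simplify = FALSE)) {
      sub <- corr[comb, comb]
      if (all(sub[upper.tri(sub)] > r_threshold))
        qualifying <- c(qualifying, list(comb))
    }
  }
  # keep maximal subsets only
  is_max <- vapply(seq_along(qualifying), function(i) {
    !any(vapply(seq_along(qualifying), function(j)
      i != j && all(qualifying[[i]] %in% qualifying[[j]]), logical(1)))
  }, logical(1))
  mods <- lapply(qualifying[is_max], function(comb) sort(ids[comb]))
  key <- vapply(mods, paste, character(1), collapse = ",")
  mods[order(-lengths(mods), key)]
}

# Random correlation-like symmetric matrix with unit diagonal.
random_corr_matrix <- function(n) {
  m <- matrix(runif(n * n, -1, 1), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  rownames(m) <- colnames(m) <- sprintf("g%02d", seq_len(n))
  m
}
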