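#' @title Gaussian mixture fitting per feature
#' @description Internal helpers and user-facing operations for fitting one-
#'   and two-component Gaussian mixtures to a single feature's expression
#'   vector, selecting between them by BIC, and re-clustering two-component
#'   features with exact one-dimensional k-means.
#' @name mixture_core
NULL

# Variance floor guarding against singular components: a small multiple of
# the sample variance so that collapsing a component onto (near-)duplicated
# points cannot drive the likelihood to infinity.
.var_floor <- function(x) 1e-4 * (stats::var(x) + 1e-8)

.new_mixture_fit <- function(k, mu, sigma, pi, loglik, bic, assignments,
                             method, n) {
  structure(list(k = k, mu = mu, sigma = sigma, pi = pi, loglik = loglik,
                 bic = bic, assignments = assignments, method = method,
                 n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit (%s, k=%d, n=%d)\n", x$method, x$k, x$n))
  cat("  mu:    ", paste(signif(x$mu, 4), collapse = ", "), "\n")
  cat("  sigma: ", paste(signif(x$sigma, 4), collapse = ", "), "\n")
  cat("  pi:    ", paste(signif(x$pi, 4), collapse = ", "), "\n")
  if (is.finite(x$bic)) cat(sprintf("  loglik: %.3f  BIC: %.3f\n",
                                    x$loglik, x$bic))
  invisible(x)
}

# Deterministic restart grid for the two-component EM: nine quantile pairs
# spanning narrow to wide splits, plus the exact 1-D 2-means split.
.em2_inits <- function(x, var_floor) {
  probs <- rbind(c(0.05, 0.95), c(0.10, 0.90), c(0.15, 0.85),
                 c(0.20, 0.80), c(0.25, 0.75), c(0.30, 0.70),
                 c(0.35, 0.65), c(0.40, 0.60), c(0.45, 0.55))
  s0 <- max(stats::sd(x) / 2, sqrt(var_floor))
  inits <- matrix(NA_real_, nrow = nrow(probs) + 1L, ncol = 5L)
  for (i in seq_len(nrow(probs))) {
    q <- stats::quantile(x, probs[i, ], names = FALSE, type = 7)
    if (q[2] - q[1] < 1e-10) q <- q + c(-1, 1) * s0   # tied quantiles
    p1 <- mean(x <= mean(q))
    inits[i, ] <- c(q[1], q[2], s0, s0, min(max(p1, 0.05), 0.95))
  }
  sp <- .best_1d_split(x)
  m1 <- mean(x[sp$lower]); m2 <- mean(x[!sp$lower])
  if (!is.finite(m2 - m1) || m2 - m1 < 1e-10) { m1 <- m1 - s0; m2 <- m2 + s0 }
  inits[nrow(inits), ] <- c(m1, m2, s0, s0,
                            min(max(mean(sp$lower), 0.05), 0.95))
  inits
}

# Exact 1-D 2-means: the optimal two-cluster partition of a 1-D vector is a
# contiguous split of the sorted values; scan all n-1 splits for the minimum
# total within-cluster sum of squares.  Ties go to the smallest split.
# Returns a logical `lower` mask (original order) and the attained SSE.
.best_1d_split <- function(x) {
  n <- length(x)
  ord <- order(x)            # stable: ties keep original order
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  j <- seq_len(n - 1L)
  n1 <- j
  n2 <- n - j
  s1 <- cs[j]
  s2 <- cs[n] - s1
  sse <- (cs2[j] - s1^2 / n1) + (cs2[n] - cs2[j] - s2^2 / n2)
  jbest <- which.min(sse)    # first minimum on ties
  lower <- logical(n)
  lower[ord[seq_len(jbest)]] <- TRUE
  list(lower = lower, sse = sse[jbest])
}

#' Fit a one- or two-component Gaussian mixture by maximum likelihood
#'
#' The one-component fit is the closed-form Gaussian MLE.  The
#' two-component fit runs the EM algorithm from 10 deterministic restarts
#' (nine quantile-pair initializations plus the exact 1-D 2-means split) and
#' keeps the restart with the highest log-likelihood.  Component variances
#' are floored at a small multiple of the sample variance; components are
#' returned sorted by mean.  BIC is `-2*loglik + p*log(n)` with `p = 2`
#' parameters for one component and `p = 5` (two means, two variances, one
#' free proportion) for two.
#'
#' @param values Numeric vector of at least 10 finite observations
#'   (log2-scale expression of one feature).
#' @param k Number of components, 1 or 2.
#' @param seed Unused by the deterministic restart grid; accepted so callers
#'   can pass one uniformly.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @return A `mixture_fit` with fields `k`, `mu`, `sigma`, `pi`, `loglik`,
#'   `bic`, `assignments` (hard labels by posterior, ties to the lower-mean
#'   component) and `method = "em"`.
#' @export
fit_em <- function(values, k, seed = NULL, max_iter = 500, tol = 1e-8) {
  if (length(values) < 10L) stop("need at least 10 observations")
  if (!all(is.finite(values))) stop("values must be finite")
  if (!k %in% c(1L, 2L)) stop("`k` must be 1 or 2")
  n <- length(values)
  vf <- .var_floor(values)
  if (k == 1L) {
    mu <- mean(values)
    s2 <- max(mean((values - mu)^2), vf)
    ll <- sum(stats::dnorm(values, mu, sqrt(s2), log = TRUE))
    return(.new_mixture_fit(1L, mu, sqrt(s2), 1, ll,
                            -2 * ll + 2 * log(n),
                            rep(1L, n), "em", n))
  }
  if (max(values) - min(values) < 1e-12)
    stop("degenerate data: all values identical; a two-component fit is undefined")
  fit <- em_gauss2_cpp(values, .em2_inits(values, vf), max_iter, tol, vf)
  assign <- ifelse(fit$resp1 >= 0.5, 1L, 2L)
  out <- .new_mixture_fit(2L, c(fit$mu1, fit$mu2), c(fit$sigma1, fit$sigma2),
                          c(fit$pi1, 1 - fit$pi1), fit$loglik,
                          -2 * fit$loglik + 5 * log(n), assign, "em", n)
  out$monotone <- fit$monotone   # per-iteration log-likelihood check
  out
}

#' Choose between one and two components by BIC
#'
#' Fits both models with [fit_em()]; the lower BIC wins.  When the
#' two-component model wins but its smaller mixing proportion is at or below
#' `pi_min` (default 0.1), the feature is set aside as driven by a handful
#' of outliers rather than called bimodal.
#'
#' @inheritParams fit_em
#' @param pi_min Both mixing proportions must exceed this for a bimodal
#'   verdict.
#' @return A `modality_verdict`: list with `modality` (`"unimodal"`,
#'   `"bimodal"` or `"excluded_proportion"`), `fit` (the selected fit), and
#'   both candidate fits `fit1`, `fit2`.
#' @export
select_model <- function(values, seed = NULL, pi_min = 0.1,
                         max_iter = 500, tol = 1e-8) {
  fit1 <- fit_em(values, 1L, seed, max_iter, tol)
  fit2 <- fit_em(values, 2L, seed, max_iter, tol)
  if (fit2$bic < fit1$bic) {
    if (min(fit2$pi) <= pi_min) {
      modality <- "excluded_proportion"
      fit <- fit2
    } else {
      modality <- "bimodal"
      fit <- fit2
    }
  } else {
    modality <- "unimodal"
    fit <- fit1
  }
  structure(list(modality = modality, fit = fit, fit1 = fit1, fit2 = fit2),
            class = "modality_verdict")
}

#' @export
print.modality_verdict <- function(x, ...) {
  cat(sprintf("modality_verdict: %s (BIC k=1: %.2f, k=2: %.2f)\n",
              x$modality, x$fit1$bic, x$fit2$bic))
  invisible(x)
}

#' Re-cluster a bimodal feature with exact 1-D k-means (k = 2)
#'
#' In one dimension the optimal 2-means partition is a contiguous split of
#' the sorted values, so the global optimum is found by scanning all splits
#' for the minimum within-cluster sum of squares — deterministic and free of
#' initialization sensitivity.  Cluster means, sample standard deviations
#' (n−1 denominator, floored) and occupancy proportions are reported as the
#' component parameters, ordered by mean.
#'
#' @param values Numeric vector (a feature already called bimodal).
#' @return A `mixture_fit` with `method = "kmeans"`, `k = 2`.
#' @export
kmeans_recluster <- function(values) {
  if (length(values) < 4L) stop("need at least 4 observations")
  if (!all(is.finite(values))) stop("values must be finite")
  sp <- .best_1d_split(values)
  n1 <- sum(sp$lower)
  n2 <- length(values) - n1
  if (min(n1, n2) < 2L)
    stop("degenerate cluster of size ", min(n1, n2),
         ": standard deviation undefined")
  sfloor <- sqrt(.var_floor(values))
  lo <- values[sp$lower]
  hi <- values[!sp$lower]
  .new_mixture_fit(
    2L,
    mu = c(mean(lo), mean(hi)),
    sigma = pmax(c(stats::sd(lo), stats::sd(hi)), sfloor),
    pi = c(n1, n2) / length(values),
    loglik = NA_real_, bic = NA_real_,
    assignments = ifelse(sp$lower, 1L, 2L),
    method = "kmeans", n = length(values))
}
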