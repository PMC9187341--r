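#' Pairwise Pearson correlations between features
#'
#' Computes the symmetric Pearson correlation matrix between the given
#' features across samples (tumor samples, on the log2 scale, in the
#' standard workflow).  Zero-variance features cannot be correlated and are
#' excluded with a warning.
#'
#' @param m An [expression_matrix()].
#' @param feature_subset Optional character vector of features to use
#'   (typically those with final bimodality index above threshold).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(m, feature_subset = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  vals <- m$values
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, rownames(vals))
    if (length(missing))
      stop("features not present: ", paste(head(missing, 3), collapse = ", "))
    vals <- vals[feature_subset, , drop = FALSE]
  }
  v <- apply(vals, 1L, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance feature(s): ",
            paste(rownames(vals)[v == 0], collapse = ", "))
    vals <- vals[v > 0, , drop = FALSE]
  }
  cor(t(vals))
}

#' Find modules of concurrently expressed features
#'
#' A module is a group of at least `min_size` features whose pairwise
#' correlations all exceed `r_threshold` (strictly).  Formally these are the
#' maximal cliques of the graph with an edge wherever `r > r_threshold`;
#' maximal cliques may overlap.  A greedy disjoint mode repeatedly takes the
#' best remaining clique and removes its members.
#'
#' @param corr_matrix Symmetric correlation matrix (from
#'   [pairwise_correlations()]).
#' @param r_threshold Strict lower bound on every within-module pairwise
#'   correlation.
#' @param min_size Minimum module size.
#' @param disjoint If `TRUE`, return non-overlapping modules greedily.
#' @return List of modules ordered by size (descending) then
#'   lexicographically; each is a list with `features` (sorted ids) and
#'   `min_pairwise_r`.
#' @export
find_modules <- function(corr_matrix, r_threshold = 0.5, min_size = 3,
                         disjoint = FALSE) {
  if (!isSymmetric(unname(corr_matrix)))
    stop("`corr_matrix` must be symmetric")
  ids <- rownames(corr_matrix)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(corr_matrix)))
  adj <- corr_matrix > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- ids
  cliques <- igraph::max_cliques(g, min = min_size)
  mods <- lapply(cliques, function(cl) {
    f <- sort(names(cl))
    sub <- corr_matrix[f, f]
    list(features = f, min_pairwise_r = min(sub[upper.tri(sub)]))
  })
  # deterministic order: size desc, then member ids
  key <- vapply(mods, function(mo) paste(mo$features, collapse = ","),
                character(1))
  ord <- order(-vapply(mods, function(mo) length(mo$features), integer(1)),
               key)
  mods <- mods[ord]
  if (disjoint && length(mods)) {
    kept <- list()
    used <- character(0)
    for (mo in mods) {
      if (!length(intersect(mo$features, used))) {
        kept <- c(kept, list(mo))
        used <- c(used, mo$features)
      }
    }
    mods <- kept
  }
  mods
}
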