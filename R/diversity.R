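#' Alpha diversity: observed ASVs and Shannon index
#'
#' `observed_asvs()` counts entries greater than zero; `shannon()` computes
#' H = -sum(p_i log p_i) over the positive entries after closing the row to
#' proportions (natural log by default, matching the common phyloseq/vegan
#' convention).
#'
#' @param x A non-negative numeric vector (one sample row) or an
#'   [abundance_table()]; for a table, one value per sample is returned.
#' @param base Logarithm base for `shannon()` (default `exp(1)`).
#' @return Integer count(s) or Shannon index value(s).
#' @export
observed_asvs <- function(x) {
  if (inherits(x, "abund_table") || is.matrix(x)) {
    if (any(rowSums(x) == 0)) stop("all-zero sample row")
    return(rowSums(unclass(x) > 0))
  }
  if (any(x < 0)) stop("negative abundances")
  if (sum(x) == 0) stop("all-zero sample row")
  sum(x > 0)
}

#' @rdname observed_asvs
#' @export
shannon <- function(x, base = exp(1)) {
  if (inherits(x, "abund_table") || is.matrix(x)) {
    if (any(rowSums(x) == 0)) stop("all-zero sample row")
    return(vegan::diversity(unclass(x), index = "shannon", base = base))
  }
  if (any(x < 0)) stop("negative abundances")
  if (sum(x) == 0) stop("all-zero sample row")
  vegan::diversity(x, index = "shannon", base = base)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i), computed on rarefied
#' abundances via [vegan::vegdist()]. Returned as a full symmetric matrix
#' with sample ids, zero diagonal and entries in `[0, 1]`.
#'
#' @param table An [abundance_table()] or numeric matrix (samples x ASVs)
#'   with at least two samples.
#' @return A symmetric `dist_matrix` (matrix subclass).
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  if (nrow(m) < 2) stop("need at least two samples")
  if (any(rowSums(m) == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Embeds samples in `k` dimensions by minimizing Kruskal stress
#' (via [vegan::metaMDS()] on the precomputed dissimilarities, best of
#' `n_restarts` random starts). Coordinates are defined only up to rotation
#' and reflection; compare stress and shapes, not raw coordinates.
#'
#' @param dm Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k Embedding dimension (default 2); must be below the sample count.
#' @param n_restarts Random restarts (default 20).
#' @param seed Seed for the restarts (default 42).
#' @return List with `points` (n x k matrix) and `stress` (Kruskal stress-1,
#'   as a fraction in `[0, 1]`).
#' @export
nmds <- function(dm, k = 2, n_restarts = 20, seed = 42) {
  m <- as.matrix(dm)
  if (k >= nrow(m)) stop("`k` must be smaller than the number of samples")
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(m), k = k, try = n_restarts,
                        trymax = n_restarts, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  list(points = fit$points, stress = fit$stress)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' One-factor permutational multivariate analysis of variance: the pseudo-F
#' statistic partitions the sum of squared dissimilarities into among- and
#' within-group components; significance comes from free permutation of the
#' group labels (via [vegan::adonis2()]). The pseudo-F is deterministic;
#' the p-value is Monte-Carlo with
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations), so its smallest
#' attainable value is 1/(n_permutations + 1).
#'
#' @param dm Symmetric dissimilarity matrix.
#' @param grouping Factor (or coercible) of group labels, one per sample;
#'   every group needs at least two members.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Seed for the permutations (default 42).
#' @return List of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `factor_name`, `df`.
#' @export
permanova <- function(dm, grouping, n_permutations = 1000, seed = 42) {
  m <- as.matrix(dm)
  grouping <- as.factor(grouping)
  if (length(grouping) != nrow(m)) stop("grouping length must match sample count")
  if (nlevels(droplevels(grouping)) < 2) stop("need at least two groups")
  if (any(table(droplevels(grouping)) < 2)) {
    stop("every group needs at least two members")
  }
  set.seed(seed)
  df <- data.frame(g = droplevels(grouping))
  fit <- vegan::adonis2(stats::as.dist(m) ~ g, data = df,
                        permutations = n_permutations)
  structure(list(pseudo_F = fit$F[1], p_value = fit$`Pr(>F)`[1],
                 n_permutations = n_permutations,
                 factor_name = deparse(substitute(grouping)),
                 df = c(among = fit$Df[1], residual = fit$Df[2])),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(x$pseudo_F, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Pairwise PERMANOVA contrasts with FDR adjustment
#'
#' Runs [permanova()] on every pair of group levels and adjusts the p-values
#' jointly by Benjamini-Hochberg; the correction family is all pairwise
#' contrasts of one call.
#'
#' @inheritParams permanova
#' @return Data frame: `group1`, `group2`, `pseudo_F`, `p_value`, `p_adj`.
#' @export
pairwise_permanova <- function(dm, grouping, n_permutations = 1000, seed = 42) {
  m <- as.matrix(dm)
  grouping <- droplevels(as.factor(grouping))
  lv <- levels(grouping)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- grouping %in% pr
    r <- permanova(m[i, i, drop = FALSE], grouping[i],
                   n_permutations = n_permutations, seed = seed)
    c(F = r$pseudo_F, p = r$p_value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    pseudo_F = res["F", ], p_value = res["p", ])
  out$p_adj <- fdr_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()] with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values, each at least as large as the raw value.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
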