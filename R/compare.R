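#' Cross-modal cluster allocation table
#'
#' Contingency of tau-cluster vs atrophy-cluster membership for the same
#' subjects, with a Pearson chi-square test of independence (hand-computed
#' statistic, no continuity correction) and row-wise sharing fractions —
#' e.g. the fraction of each tau cluster falling in each atrophy cluster.
#'
#' @param p_tau,p_atrophy named label vectors over the same subjects (names
#'   are subject ids; unnamed vectors are matched by position).
#' @return list of class `"allocation_table"`: `counts`, `chisq`, `df`,
#'   `p_value`, `row_fractions`.
#' @export
allocation_overlap <- function(p_tau, p_atrophy) {
  if (!is.null(names(p_tau)) && !is.null(names(p_atrophy))) {
    shared <- intersect(names(p_tau), names(p_atrophy))
    if (length(shared) == 0L) stop("disjoint subject sets")
    p_tau <- p_tau[shared]
    p_atrophy <- p_atrophy[shared]
  } else if (length(p_tau) != length(p_atrophy)) {
    stop("partitions must cover the same subjects")
  }
  counts <- table(tau = p_tau, atrophy = p_atrophy)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  if (df == 0L)
    stop("degenerate table: chi-square undefined with a single cluster")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5))
    warning("expected counts < 5; chi-square approximation is weak")
  chisq <- sum((counts - expected)^2 / expected)
  list_out <- list(counts = counts, chisq = chisq, df = df,
                   p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                   row_fractions = sweep(counts, 1L, rowSums(counts), "/"))
  structure(list_out, class = "allocation_table")
}

#' Per-cluster mean ROI profiles
#'
#' Unweighted mean z-score per ROI over each cluster's members.
#'
#' @param z_roi subjects x ROI matrix of z-scores.
#' @param partition label vector over the rows of `z_roi`.
#' @return clusters x ROI matrix, rows named by cluster label.
#' @export
cluster_roi_profile <- function(z_roi, partition) {
  z_roi <- as.matrix(z_roi)
  if (length(partition) != nrow(z_roi))
    stop("partition must cover all rows")
  f <- factor(partition)
  if (any(table(f) == 0L)) stop("empty cluster")
  out <- rowsum(z_roi, f, reorder = TRUE) / as.vector(table(f))
  rownames(out) <- levels(f)
  out
}

#' Spearman coupling of cluster profiles across modalities
#'
#' Rank-correlates every tau-cluster ROI profile with every atrophy-cluster
#' ROI profile over the shared ROI set. Because lower thickness/volume means
#' more atrophy while higher tau uptake means more pathology, the atrophy
#' profiles are multiplied by -1 before ranking (`flip_sign`), so positive
#' rho means spatially coupled abnormality. P-values are Bonferroni-adjusted
#' over all cells.
#'
#' @param tau_profiles,atrophy_profiles clusters x ROI matrices sharing
#'   column names (>= 5 shared ROIs required).
#' @param flip_sign multiply atrophy profiles by -1 (default `TRUE`; set
#'   `FALSE` if the input is already an abnormality score).
#' @return list of class `"crossmodal_result"`: `rho` (tau clusters x
#'   atrophy clusters), `p_value`, `p_bonferroni`, `n_roi`.
#' @export
crossmodal_spearman <- function(tau_profiles, atrophy_profiles,
                                flip_sign = TRUE) {
  shared <- intersect(colnames(tau_profiles), colnames(atrophy_profiles))
  if (length(shared) < 5L)
    stop("need >= 5 shared ROIs for a stable rank correlation")
  A <- as.matrix(tau_profiles)[, shared, drop = FALSE]
  B <- as.matrix(atrophy_profiles)[, shared, drop = FALSE]
  if (flip_sign) B <- -B
  kt <- nrow(A); ka <- nrow(B)
  rho <- p <- matrix(NA_real_, kt, ka,
                     dimnames = list(rownames(A), rownames(B)))
  for (i in seq_len(kt)) for (j in seq_len(ka)) {
    ct <- suppressWarnings(
      stats::cor.test(A[i, ], B[j, ], method = "spearman", exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  structure(list(rho = rho, p_value = p,
                 p_bonferroni = pmin(1, p * length(p)),
                 n_roi = length(shared)),
            class = "crossmodal_result")
}

# Pooled-variance two-sample t statistics for all features at once, for
# n_perm label permutations. `ga` is a 0/1 indicator matrix (n_perm x n)
# selecting group A in each permutation.
perm_t_stats <- function(X, ga, na, nb) {
  tot <- colSums(X); tot2 <- colSums(X^2)
  SA <- ga %*% X
  SA2 <- ga %*% (X^2)
  SB <- matrix(tot, nrow(ga), ncol(X), byrow = TRUE) - SA
  SB2 <- matrix(tot2, nrow(ga), ncol(X), byrow = TRUE) - SA2
  va <- (SA2 - SA^2 / na) / (na - 1)
  vb <- (SB2 - SB^2 / nb) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  sp2[sp2 < .Machine$double.eps] <- .Machine$double.eps
  (SA / na - SB / nb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Permutation contrast map with max-statistic FWE control
#'
#' Per-feature two-sample pooled-variance t statistics, with family-wise
#' error control by the permutation distribution of the maximum absolute t
#' over features under group-label shuffles. Max-statistic FWE is exact
#' under exchangeability and needs no mesh geometry (it replaces
#' cluster-enhancement methods that do).
#'
#' @param z subjects x features matrix.
#' @param group_a,group_b disjoint index or id vectors into the rows of `z`,
#'   each of size >= 2.
#' @param n_perm number of label permutations (>= 100).
#' @param alpha FWE significance level for the mask.
#' @param seed permutation seed.
#' @return list of class `"contrast_map"`: `t` (observed statistics),
#'   `p_fwe`, `mask` (corrected p < alpha), `contrast` descriptor.
#' @export
contrast_map <- function(z, group_a, group_b, n_perm = 1000L, alpha = 0.05,
                         seed = 1L) {
  z <- as.matrix(z)
  if (is.character(group_a)) group_a <- match(group_a, rownames(z))
  if (is.character(group_b)) group_b <- match(group_b, rownames(z))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 subjects")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm >= 100 required for FWE resolution")
  X <- z[c(group_a, group_b), , drop = FALSE]
  n <- na + nb
  obs <- drop(perm_t_stats(X, matrix(c(rep(1, na), rep(0, nb)), 1L), na, nb))
  withr_seed(seed, {
    ga <- matrix(0, n_perm, n)
    for (b in seq_len(n_perm)) ga[b, sample.int(n, na)] <- 1
  })
  null_max <- apply(abs(perm_t_stats(X, ga, na, nb)), 1L, max)
  p_fwe <- vapply(abs(obs), function(t0) (1 + sum(null_max >= t0)) /
                    (n_perm + 1), numeric(1L))
  structure(list(t = obs, p_fwe = p_fwe, mask = p_fwe < alpha,
                 alpha = alpha, n_perm = n_perm,
                 contrast = "group_a vs group_b (two-tailed)"),
            class = "contrast_map")
}

#' Cluster-vs-rest contrast maps ("most" and "least" abnormal regions)
#'
#' For each cluster with at least 2 members, contrasts the cluster against
#' all remaining subjects; features significantly higher in the cluster form
#' the "most" mask and significantly lower the "least" mask. Singleton
#' clusters are skipped with a warning.
#'
#' @param z subjects x features matrix.
#' @param partition label vector over the rows of `z`.
#' @inheritParams contrast_map
#' @return named list per cluster, each a list with the full `contrast_map`
#'   plus `most` and `least` logical masks; clusters that were skipped are
#'   absent.
#' @export
most_least_maps <- function(z, partition, n_perm = 1000L, alpha = 0.05,
                            seed = 1L) {
  labs <- sort(unique(partition))
  if (length(labs) < 2L) {
    warning("single-cluster partition: no contrasts computed")
    return(list())
  }
  out <- list()
  for (l in labs) {
    idx <- which(partition == l)
    if (length(idx) < 2L || length(partition) - length(idx) < 2L) {
      warning("cluster ", l, " leaves < 2 subjects on one side; skipped")
      next
    }
    cm <- contrast_map(z, idx, setdiff(seq_along(partition), idx),
                       n_perm = n_perm, alpha = alpha, seed = seed)
    cm$contrast <- paste0("cluster ", l, " vs rest (two-tailed)")
    out[[as.character(l)]] <- c(cm, list(most = cm$mask & cm$t > 0,
                                         least = cm$mask & cm$t < 0))
  }
  out
}

#' Vertex-wise cross-modal correlation map with FWE control
#'
#' Correlates tau and thickness z-scores per feature across subjects,
#' controlling the family-wise error by the permutation distribution of the
#' maximum absolute correlation under subject shuffles of one modality.
#' Constant feature columns are excluded and reported.
#'
#' @param z_tau,z_thickness subjects x features matrices over the same
#'   subjects and features.
#' @param subset optional row indices/ids restricting the subjects used.
#' @inheritParams contrast_map
#' @return list of class `"correlation_map"`: `r`, `p_fwe`, `mask`,
#'   `excluded` (constant features).
#' @export
vertexwise_correlation <- function(z_tau, z_thickness, subset = NULL,
                                   n_perm = 1000L, alpha = 0.05, seed = 1L) {
  A <- as.matrix(z_tau); B <- as.matrix(z_thickness)
  if (!all(dim(A) == dim(B)))
    stop("matrices must share subjects and features")
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- match(subset, rownames(A))
    A <- A[subset, , drop = FALSE]; B <- B[subset, , drop = FALSE]
  }
  n <- nrow(A)
  if (n < 5L) stop("need >= 5 subjects")
  sd0 <- function(M) apply(M, 2L, stats::sd)
  const <- sd0(A) < .Machine$double.eps | sd0(B) < .Machine$double.eps
  excluded <- which(const)
  if (length(excluded))
    message(length(excluded), " constant feature column(s) excluded")
  A <- scale(A[, !const, drop = FALSE]); B <- scale(B[, !const, drop = FALSE])
  r_of <- function(M) colSums(M * B) / (n - 1)
  obs <- r_of(A)
  withr_seed(seed, {
    null_max <- vapply(seq_len(n_perm), function(b)
      max(abs(r_of(A[sample.int(n), , drop = FALSE]))), numeric(1L))
  })
  p_fwe <- vapply(abs(obs), function(r0) (1 + sum(null_max >= r0)) /
                    (n_perm + 1), numeric(1L))
  structure(list(r = obs, p_fwe = p_fwe, mask = p_fwe < alpha,
                 alpha = alpha, n_perm = n_perm, excluded = excluded),
            class = "correlation_map")
}
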