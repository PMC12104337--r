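#' Subject-by-subject similarity matrix from z-score maps
#'
#' Correlates every pair of subjects' abnormality z-score vectors, yielding
#' the weighted graph on which community detection runs. Pearson correlation
#' is the default reading of "correlation between z-score vectors"; Spearman
#' is available for heavy-tailed maps.
#'
#' @param z numeric matrix, subjects x features (vertices or ROIs); row names
#'   are subject ids.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a symmetric subjects x subjects matrix of class
#'   `"subject_similarity"` with unit diagonal.
#' @examples
#' z <- matrix(rnorm(5 * 40), 5, 40, dimnames = list(paste0("s", 1:5), NULL))
#' S <- similarity_matrix(z)
#' @export
similarity_matrix <- function(z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  z <- as.matrix(z)
  if (nrow(z) < 3L) stop("need at least 3 subjects")
  if (ncol(z) < 2L) stop("need at least 2 features")
  rv <- apply(z, 1L, stats::var)
  if (any(rv < .Machine$double.eps)) {
    bad <- rownames(z)[rv < .Machine$double.eps]
    if (is.null(bad)) bad <- which(rv < .Machine$double.eps)
    stop("zero-variance z rows for subject(s): ", paste(bad, collapse = ", "))
  }
  S <- stats::cor(t(z), method = method)
  S <- (S + t(S)) / 2            # exact symmetry
  diag(S) <- 1
  dimnames(S) <- list(rownames(z), rownames(z))
  structure(S, class = c("subject_similarity", "matrix", "array"),
            method = method)
}

#' Clustering configuration
#'
#' Bundle of consensus-clustering settings. Defaults follow the reference
#' analysis: 1,000 Louvain restarts aggregated through a co-assignment
#' matrix; resolution gamma must be chosen per modality (1.2 for tau and
#' 1.32 for atrophy reproduced a four-cluster solution in the source cohort).
#'
#' @param gamma positive resolution parameter; larger values favour more,
#'   smaller communities.
#' @param n_iterations number of independent Louvain restarts per consensus
#'   round.
#' @param coassignment_threshold entries of the co-assignment matrix below
#'   this fraction are zeroed before re-clustering; in (0, 1).
#' @param max_consensus_rounds abort with an error if the co-assignment
#'   matrix has not become binary block-structured after this many rounds.
#' @param negative_weight_policy `"clip_zero"` (default) zeroes negative
#'   similarities before modularity; `"signed"` passes them through
#'   unchanged (experimental).
#' @param seed master seed; restart seeds are derived from it.
#' @return list of class `"clustering_config"`.
#' @export
clustering_config <- function(gamma = 1.2, n_iterations = 1000L,
                              coassignment_threshold = 0.5,
                              max_consensus_rounds = 100L,
                              negative_weight_policy = c("clip_zero", "signed"),
                              seed = 1L) {
  negative_weight_policy <- match.arg(negative_weight_policy)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma <= 0) stop("gamma must be > 0")
  if (coassignment_threshold <= 0 || coassignment_threshold >= 1)
    stop("coassignment_threshold must be in (0, 1)")
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(list(gamma = gamma, n_iterations = n_iterations,
                 coassignment_threshold = coassignment_threshold,
                 max_consensus_rounds = as.integer(max_consensus_rounds),
                 negative_weight_policy = negative_weight_policy,
                 seed = as.integer(seed)),
            class = "clustering_config")
}

# Prepare a similarity matrix for modularity optimisation: drop the
# self-similarity diagonal and apply the negative-weight policy.
prep_weights <- function(S, policy = "clip_zero") {
  W <- unclass(as.matrix(S))
  diag(W) <- 0
  if (policy == "clip_zero") {
    neg <- W < 0
    frac <- mean(neg)
    W[neg] <- 0
    attr(W, "clipped_fraction") <- frac
  }
  W
}

#' Weighted Newman-Girvan modularity with resolution parameter
#'
#' \deqn{Q = \frac{1}{2m}\sum_{i \ne j}\left[w_{ij} -
#'   \gamma \frac{k_i k_j}{2m}\right]\delta(c_i, c_j)}
#' Self-weights are excluded; `m` is the total edge weight.
#'
#' @param S symmetric weight matrix (diagonal ignored).
#' @param labels integer community labels, one per node.
#' @param gamma resolution parameter.
#' @param negative_weight_policy see [clustering_config()].
#' @return scalar Q.
#' @export
modularity_q <- function(S, labels, gamma = 1,
                         negative_weight_policy = "clip_zero") {
  W <- prep_weights(S, negative_weight_policy)
  n <- nrow(W)
  if (length(labels) != n) stop("labels length must match matrix size")
  two_m <- sum(W)
  if (two_m <= 0) stop("total edge weight must be positive")
  k <- rowSums(W)
  win <- tapply(seq_len(n), labels, function(idx)
    sum(W[idx, idx, drop = FALSE]))
  tot <- tapply(k, labels, sum)
  sum(win) / two_m - gamma * sum((tot / two_m)^2)
}

# Relabel so cluster 1 is the largest (ties: first-appearing), labels 1..k.
canonicalize_labels <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.vector(tab), match(names(tab), unique(as.character(labels))))]
  out <- match(as.character(labels), ord)
  names(out) <- names(labels)
  out
}

#' Single Louvain partition
#'
#' One stochastic run of greedy modularity maximisation (local moves +
#' graph aggregation). The node visit order is shuffled from `seed`, so
#' different seeds can land in different local optima; use
#' [consensus_cluster()] for a stable solution.
#'
#' @inheritParams modularity_q
#' @param seed integer seed for the visit-order shuffle.
#' @return list of class `"partition_result"`: `labels` (1-based, largest
#'   cluster first), `modularity`, `gamma`, `seed`, `n_communities`.
#' @export
louvain_partition <- function(S, gamma = 1, seed = 1L,
                              negative_weight_policy = "clip_zero") {
  if (gamma <= 0) stop("gamma must be > 0")
  W <- prep_weights(S, negative_weight_policy)
  res <- .louvain_cpp(W, gamma, as.integer(seed))
  labels <- canonicalize_labels(res$labels)
  names(labels) <- rownames(W)
  structure(list(labels = labels, modularity = res$modularity,
                 gamma = gamma, seed = as.integer(seed),
                 n_communities = res$n_communities),
            class = "partition_result")
}

# Is a co-assignment matrix binary with clean block structure?
is_binary_blocked <- function(D, tol = 1e-12) {
  if (any(D > tol & D < 1 - tol)) return(FALSE)
  B <- D >= 1 - tol
  comp <- block_components(B)
  all(B == outer(comp, comp, "==") | !B) &&
    all(B[outer(comp, comp, "==")])
}

# Connected components of a logical adjacency matrix (diag TRUE).
block_components <- function(B) {
  n <- nrow(B)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      frontier <- i
      comp[i] <- cur
      while (length(frontier)) {
        nb <- which(colSums(B[frontier, , drop = FALSE]) > 0 & comp == 0L)
        comp[nb] <- cur
        frontier <- nb
      }
    }
  }
  comp
}

#' Consensus clustering over Louvain restarts
#'
#' Runs Louvain `n_iterations` times with distinct seeds, records for every
#' subject pair the fraction of runs in which they were co-assigned, zeroes
#' fractions below `coassignment_threshold`, and re-clusters the thresholded
#' co-assignment matrix; the cycle repeats until the co-assignment matrix is
#' binary block-structured (all restarts agree), following the
#' consensus-matrix iteration scheme of Lancichinetti & Fortunato. Run on a
#' full cohort, the result is the Consensus Initial Partition (CIP) used as
#' the reference in [loo_stability()].
#'
#' @param S `subject_similarity` (or any symmetric weight matrix).
#' @param config a [clustering_config()].
#' @return list of class `"consensus_partition"`: `labels`, `k`,
#'   `coassignment` (first-round co-assignment fractions on the input
#'   graph), `rounds`, `gamma`, `n_iterations`, `seed`.
#' @export
consensus_cluster <- function(S, config = clustering_config()) {
  stopifnot(inherits(config, "clustering_config"))
  W <- prep_weights(S, config$negative_weight_policy)
  n <- nrow(W)
  ids <- rownames(W)
  seed_base <- as.integer(config$seed)

  run_round <- function(M, round) {
    L <- matrix(0L, n, config$n_iterations)
    for (it in seq_len(config$n_iterations)) {
      # double-precision arithmetic: exact far beyond 2^31, no overflow
      s <- as.integer((as.numeric(seed_base) * 1009 + round * 131071 + it) %%
                        2147483647)
      L[, it] <- .louvain_cpp(M, config$gamma, s)$labels
    }
    D <- matrix(0, n, n)
    for (it in seq_len(config$n_iterations))
      D <- D + outer(L[, it], L[, it], "==")
    D / config$n_iterations
  }

  M <- W
  coassign1 <- NULL
  for (round in seq_len(config$max_consensus_rounds)) {
    if (sum(M) <= 0) {
      # nothing left to cluster: every subject is its own community
      labels <- seq_len(n)
      names(labels) <- ids
      return(structure(list(labels = labels, k = n,
                            coassignment = if (is.null(coassign1)) diag(n) else coassign1,
                            rounds = round, gamma = config$gamma,
                            n_iterations = config$n_iterations,
                            seed = config$seed),
                       class = "consensus_partition"))
    }
    D <- run_round(M, round)
    diag(D) <- 1
    if (is.null(coassign1)) {
      coassign1 <- D
      dimnames(coassign1) <- list(ids, ids)
    }
    if (is_binary_blocked(D)) {
      labels <- canonicalize_labels(block_components(D >= 0.5))
      names(labels) <- ids
      return(structure(list(labels = labels, k = length(unique(labels)),
                            coassignment = coassign1, rounds = round,
                            gamma = config$gamma,
                            n_iterations = config$n_iterations,
                            seed = config$seed),
                       class = "consensus_partition"))
    }
    M <- D
    M[M < config$coassignment_threshold] <- 0
    diag(M) <- 0
  }
  stop("consensus did not converge after ", config$max_consensus_rounds,
       " rounds (gamma = ", config$gamma,
       "; last co-assignment range ",
       paste(signif(range(D[upper.tri(D)]), 3), collapse = " - "), ")")
}

#' Smallest resolution parameter reaching a target cluster count
#'
#' Evaluates consensus clustering over an ascending gamma grid and returns
#' the smallest grid value whose consensus partition has exactly `target_k`
#' clusters — the "smallest possible gamma for the given number of clusters"
#' selection rule.
#'
#' @inheritParams consensus_cluster
#' @param target_k desired number of clusters (>= 2).
#' @param grid ascending vector of candidate gamma values. The default step
#'   0.02 matches the precision of the published per-modality values.
#' @return list of class `"gamma_search"`: `gamma` (the selected value),
#'   `partition` (its `consensus_partition`), `k_by_gamma` (named vector of
#'   cluster counts for every evaluated grid value, in ascending order up to
#'   and including the selected gamma).
#' @export
gamma_search <- function(S, target_k, grid = seq(0.8, 2, by = 0.02),
                         config = clustering_config()) {
  if (length(grid) == 0L) stop("gamma grid is empty")
  if (is.unsorted(grid)) stop("gamma grid must be ascending")
  if (any(grid <= 0)) stop("gamma values must be > 0")
  target_k <- as.integer(target_k)
  if (target_k < 2L) stop("target_k must be >= 2")
  if (target_k > nrow(S))
    stop("no-solution: target_k (", target_k, ") exceeds number of subjects (",
         nrow(S), ")")
  ks <- stats::setNames(rep(NA_integer_, length(grid)), format(grid))
  for (g in seq_along(grid)) {
    cfg <- config
    cfg$gamma <- grid[g]
    part <- consensus_cluster(S, cfg)
    ks[g] <- part$k
    if (part$k == target_k) {
      return(structure(list(gamma = grid[g], partition = part,
                            k_by_gamma = ks[seq_len(g)]),
                       class = "gamma_search"))
    }
  }
  stop("no-solution: no grid gamma yields k = ", target_k,
       "; observed k by gamma: ",
       paste(names(ks), "->", ks, collapse = ", "))
}

#' @exportS3Method base::print
print.partition_result <- function(x, ...) {
  cat("Louvain partition: ", x$n_communities, " communities, Q = ",
      signif(x$modularity, 4), " (gamma = ", x$gamma, ", seed = ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.consensus_partition <- function(x, ...) {
  cat("Consensus partition: k = ", x$k, " (gamma = ", x$gamma, ", ",
      x$n_iterations, " iterations, ", x$rounds, " round(s))\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}
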