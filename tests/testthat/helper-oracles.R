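# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately brute-force and kept independent of the
# package implementations it checks.

# All set partitions of n items as label vectors (restricted growth strings).
enum_partitions <- function(n) {
  out <- list()
  rec <- function(pref, maxl) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return()
    }
    for (l in seq_len(maxl + 1L)) rec(c(pref, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# Modularity by direct double loop: edge term over i != j, null term over
# all pairs (self-weights excluded, degrees keep the diagonal of the null).
brute_modularity <- function(W, labels, gamma = 1) {
  diag(W) <- 0
  two_m <- sum(W)
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) {
      w <- if (i == j) 0 else W[i, j]
      q <- q + w - gamma * k[i] * k[j] / two_m
    }
  }
  q / two_m
}

# Rand index by explicit pair enumeration.
brute_rand_index <- function(p, q) {
  n <- length(p)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    total <- total + 1L
    same_p <- p[i] == p[j]
    same_q <- q[i] == q[j]
    if (same_p == same_q) agree <- agree + 1L
  }
  agree / total
}

# Pearson correlation from the covariance formula, no stats::cor.
brute_correlation <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Block-structured similarity matrix with planted communities.
planted_similarity <- function(sizes, within = 0.8, between = 0.1,
                               noise = 0, seed = 1) {
  blocks <- rep(seq_along(sizes), sizes)
  n <- length(blocks)
  S <- matrix(between, n, n)
  S[outer(blocks, blocks, "==")] <- within
  if (noise > 0) {
    set.seed(seed)
    E <- matrix(rnorm(n * n, 0, noise), n, n)
    S <- S + (E + t(E)) / 2
  }
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("s", seq_len(n))
  attr(S, "blocks") <- blocks
  S
}

# Weighted planted-partition graph: the oracle-equivalence ensemble
# (structured regime the clustering engine targets).
gen_planted_graph <- function() {
  n <- sample(4:8, 1L)
  k <- sample(1:3, 1L)
  blocks <- sort(sample(k, n, replace = TRUE))
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- if (blocks[i] == blocks[j]) runif(1, 0.5, 1)
    else runif(1, 0, 0.3) * (runif(1) < 0.6)
    W[i, j] <- W[j, i] <- w
  }
  W
}

# Structureless weighted Erdos-Renyi graph (worst case for consensus).
gen_er_graph <- function(p = 0.5) {
  n <- sample(4:8, 1L)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- runif(sum(ut)) * (runif(sum(ut)) < p)
  W + t(W)
}

# Small high-SNR cohort for fast end-to-end tests.
small_spec <- function(seed = 1, ...) {
  cohort_spec(n_hc = 60L, n_ads = 80L, cluster_sizes = c(30L, 25L, 15L, 10L),
              n_vertices = 250L, n_parcels = 10L, seed = seed, ...)
}

# Z-score both modalities of a cohort against its own HC group.
cohort_zscores <- function(cohort) {
  hc <- cohort$metadata$group == "HC"
  list(tau = vertex_zscores(cohort$tau[!hc, , drop = FALSE],
                            fit_reference(cohort$tau[hc, , drop = FALSE]),
                            modality = "tau"),
       thickness = vertex_zscores(cohort$thickness[!hc, , drop = FALSE],
                                  fit_reference(cohort$thickness[hc, ,
                                                                 drop = FALSE]),
                                  modality = "thickness"))
}
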