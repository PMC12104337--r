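#' Rand Index
#'
#' Fraction of item pairs on which two partitions agree: co-clustered in
#' both or separated in both. Computed from the contingency table, so it is
#' exact for any label encoding.
#'
#' @param p,q label vectors over the same items.
#' @return RI in \[0, 1\].
#' @export
rand_index <- function(p, q) {
  if (length(p) != length(q)) stop("partitions must cover the same items")
  n <- length(p)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(p, q)
  a <- rowSums(tab); b <- colSums(tab)
  total <- choose(n, 2)
  disagree <- (sum(a^2) + sum(b^2)) / 2 - sum(tab^2)
  (total - disagree) / total
}

#' Adjusted Rand Index
#'
#' Chance-corrected pair agreement via the standard contingency
#' formulation: 1 for identical partitions, about 0 for independent ones.
#'
#' @inheritParams rand_index
#' @return ARI (at most 1; can be negative).
#' @export
adjusted_rand_index <- function(p, q) {
  if (length(p) != length(q)) stop("partitions must cover the same items")
  n <- length(p)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(p, q)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)  # both partitions all-singletons or all-one
  (sij - expected) / (maxi - expected)
}

#' Stability-evaluation configuration
#'
#' @param removal_sizes numbers of subjects to leave out (reference
#'   protocol: 1..33 out of 166).
#' @param reps_per_size random repetitions per removal size (reference: 10).
#' @param master_seed seed controlling all removal draws and reclustering
#'   seeds.
#' @return list of class `"stability_config"`.
#' @export
stability_config <- function(removal_sizes = 1:33, reps_per_size = 10L,
                             master_seed = 1L) {
  structure(list(removal_sizes = as.integer(removal_sizes),
                 reps_per_size = as.integer(reps_per_size),
                 master_seed = as.integer(master_seed)),
            class = "stability_config")
}

#' Leave-one-out stability of a consensus partition
#'
#' Computes the Consensus Initial Partition (CIP) on the full z-score
#' matrix, then for each removal size and repetition drops that many
#' subjects at random, rebuilds the similarity matrix from the remaining
#' rows, re-runs consensus clustering at the unchanged gamma, and scores
#' the Rand Index against the CIP restricted to the retained subjects.
#'
#' @param z subjects x features z-score matrix (patients only).
#' @param gamma resolution parameter, held fixed between CIP and all
#'   leave-out runs.
#' @param stab a [stability_config()].
#' @param config a [clustering_config()]; its `gamma` is overridden by
#'   `gamma`.
#' @return list of class `"stability_report"`: `results` (data.frame size,
#'   rep, ri), `medians` (median RI per size), `cip` (the consensus
#'   partition of the full cohort).
#' @export
loo_stability <- function(z, gamma, stab = stability_config(),
                          config = clustering_config()) {
  stopifnot(inherits(stab, "stability_config"))
  n <- nrow(z)
  if (any(stab$removal_sizes >= n))
    stop("removal sizes must be smaller than the number of subjects")
  cfg <- config
  cfg$gamma <- gamma
  cip <- consensus_cluster(similarity_matrix(z), cfg)
  rows <- list()
  for (size in stab$removal_sizes) {
    for (rep_i in seq_len(stab$reps_per_size)) {
      run_seed <- as.integer((as.numeric(stab$master_seed) * 2654435 +
                                size * 40503 + rep_i) %% 2147483647)
      if (size == 0L) {
        keep <- seq_len(n)
        labels <- cip$labels
      } else {
        withr_seed(run_seed, {
          keep <- sort(sample.int(n, n - size))
        })
        cfg$seed <- run_seed
        labels <- consensus_cluster(similarity_matrix(z[keep, , drop = FALSE]),
                                    cfg)$labels
      }
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, rep = rep_i,
        ri = rand_index(labels, cip$labels[keep]))
    }
  }
  results <- do.call(rbind, rows)
  medians <- tapply(results$ri, results$size, stats::median)
  structure(list(results = results,
                 medians = data.frame(size = as.integer(names(medians)),
                                      median_ri = as.numeric(medians)),
                 cip = cip),
            class = "stability_report")
}

#' @exportS3Method base::print
print.stability_report <- function(x, ...) {
  cat("LOO stability over", length(unique(x$results$size)),
      "removal size(s); overall median RI =",
      signif(stats::median(x$results$ri), 4), "\n")
  print(x$medians, row.names = FALSE)
  invisible(x)
}
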