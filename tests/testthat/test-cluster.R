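test_that("similarity matrix equals the hand-rolled correlation oracle", {
  set.seed(1)
  z <- matrix(rnorm(5 * 100), 5, 100, dimnames = list(paste0("s", 1:5), NULL))
  S <- similarity_matrix(z)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(S[i, j], brute_correlation(z[i, ], z[j, ]),
                 tolerance = 1e-12)
  expect_equal(unname(diag(S)), rep(1, 5))
  expect_equal(S, t(S), tolerance = 0)

  z2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  S2 <- similarity_matrix(z2)
  expect_equal(S2["a", "b"], 1)
  expect_equal(S2["a", "c"], -1)

  zc <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 1, 3))
  expect_error(similarity_matrix(zc), "zero-variance.*a")
  expect_error(similarity_matrix(z[1:2, ]), "at least 3 subjects")
})

test_that("modularity matches worked examples and the brute-force oracle", {
  tri2 <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  tri2[edges] <- 1
  tri2 <- tri2 + t(tri2)
  expect_equal(modularity_q(tri2, c(1, 1, 1, 2, 2, 2), 1), 0.5)
  expect_equal(modularity_q(tri2, rep(1, 6), 1), 0)
  expect_equal(modularity_q(tri2, 1:6, 1), -1 / 6)

  set.seed(7)
  for (rep_i in 1:20) {
    W <- gen_er_graph()
    if (sum(W) == 0) next
    labels <- sample(3, nrow(W), replace = TRUE)
    gamma <- runif(1, 0.5, 2)
    expect_equal(modularity_q(W, labels, gamma),
                 brute_modularity(W, labels, gamma), tolerance = 1e-12)
  }
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "positive")
})

test_that("louvain recovers planted structure and reports its own Q", {
  cliq <- planted_similarity(c(5, 5), within = 1, between = 0)
  diag(cliq) <- 1
  for (s in 1:5) {
    p <- louvain_partition(cliq, gamma = 1, seed = s)
    expect_equal(adjusted_rand_index(p$labels, attr(cliq, "blocks")), 1)
  }

  S <- planted_similarity(c(20, 20, 20, 20))
  p <- louvain_partition(S, gamma = 1, seed = 11)
  expect_equal(adjusted_rand_index(p$labels, attr(S, "blocks")), 1)
  expect_equal(p$modularity, modularity_q(S, p$labels, 1), tolerance = 1e-12)

  # resolution sweep: higher gamma never yields fewer communities on a
  # weak two-block structure
  weak <- planted_similarity(c(15, 15), within = 0.4, between = 0.25,
                             noise = 0.05, seed = 4)
  for (s in 1:5) {
    k1 <- louvain_partition(weak, gamma = 1, seed = s)$n_communities
    k10 <- louvain_partition(weak, gamma = 10, seed = s)$n_communities
    expect_gte(k10, k1)
  }
})

test_that("louvain agrees with igraph on planted-structure graphs", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep_i in 1:10) {
    W <- gen_planted_graph()
    if (sum(W) == 0) next
    q_ours <- max(vapply(1:10, function(s)
      louvain_partition(W, gamma = 1, seed = s * 13 + rep_i)$modularity,
      numeric(1)))
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    qi <- max(vapply(1:10, function(i)
      igraph::modularity(g, igraph::membership(igraph::cluster_louvain(g)),
                         weights = igraph::E(g)$weight), numeric(1)))
    expect_equal(q_ours, qi, tolerance = 1e-9)
  }
})

test_that("consensus clustering converges, is invariant and deterministic", {
  S <- planted_similarity(c(20, 20, 20, 20))
  cfg <- clustering_config(gamma = 1.2, n_iterations = 100, seed = 5)
  cc <- consensus_cluster(S, cfg)
  # all restarts identical on clean blocks: one round, binary co-assignment
  expect_identical(cc$rounds, 1L)
  expect_true(all(cc$coassignment %in% c(0, 1)))
  expect_equal(adjusted_rand_index(cc$labels, attr(S, "blocks")), 1)

  # across master seeds
  for (s in 1:10) {
    cfg_s <- clustering_config(gamma = 1.2, n_iterations = 50, seed = s)
    cs <- consensus_cluster(S, cfg_s)
    expect_equal(adjusted_rand_index(cs$labels, attr(S, "blocks")), 1)
  }

  # determinism: identical config implies identical output
  expect_identical(consensus_cluster(S, cfg)$labels, cc$labels)

  # consensus idempotence: a binary block matrix reproduces its blocks
  blocks <- rep(1:3, c(4, 3, 5))
  D <- outer(blocks, blocks, function(a, b) as.numeric(a == b))
  rownames(D) <- colnames(D) <- paste0("s", seq_along(blocks))
  ccd <- consensus_cluster(D, clustering_config(gamma = 1, n_iterations = 30,
                                                seed = 2))
  expect_equal(adjusted_rand_index(ccd$labels, blocks), 1)

  # label-permutation invariance: permuting subjects permutes labels
  perm <- sample(nrow(S))
  Sp <- S[perm, perm]
  ccp <- consensus_cluster(Sp, cfg)
  expect_equal(adjusted_rand_index(ccp$labels, cc$labels[perm]), 1)

  # pure noise still returns a labelling
  set.seed(9)
  zn <- matrix(rnorm(30 * 60), 30, 60, dimnames = list(paste0("n", 1:30), NULL))
  ccn <- consensus_cluster(similarity_matrix(zn),
                           clustering_config(gamma = 1.2, n_iterations = 40,
                                             seed = 1))
  expect_identical(length(ccn$labels), 30L)
})

test_that("gamma search returns the smallest grid value hitting target k", {
  cliq <- planted_similarity(c(6, 6), within = 1, between = 0)
  gs <- gamma_search(cliq, target_k = 2, grid = 1.0,
                     config = clustering_config(n_iterations = 30, seed = 1))
  expect_equal(gs$gamma, 1.0)
  expect_equal(gs$partition$k, 2L)

  S <- planted_similarity(c(20, 20, 20, 20))
  cfg <- clustering_config(n_iterations = 40, seed = 3)
  grid <- c(0.8, 1.0, 1.2, 1.4)
  gs4 <- gamma_search(S, target_k = 4, grid = grid, config = cfg)
  # contract verified by exhaustive independent evaluation of the grid
  k_all <- vapply(grid, function(g) {
    cfg_g <- cfg; cfg_g$gamma <- g
    consensus_cluster(S, cfg_g)$k
  }, integer(1))
  expect_equal(gs4$gamma, grid[match(4L, k_all)])
  expect_false(any(k_all[grid < gs4$gamma] == 4L))

  expect_error(gamma_search(S, target_k = 100, grid = grid, config = cfg),
               "no-solution")
  expect_error(gamma_search(cliq, target_k = 3, grid = 1.0,
                            config = clustering_config(n_iterations = 20,
                                                       seed = 1)),
               "no-solution.*k")
  expect_error(gamma_search(S, 4, grid = numeric(0)), "empty")
})
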