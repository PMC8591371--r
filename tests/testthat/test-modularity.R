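test_that("modularity score matches closed forms and the double-sum oracle", {
  g2 <- matrix(0, 8, 8)
  g2[1:4, 1:4] <- 1; g2[5:8, 5:8] <- 1; diag(g2) <- 0
  # whole graph in one module at gamma 1: sum A = sum P
  expect_equal(modularity_score(g2, rep(1, 8), gamma = 1), 0, tolerance = 1e-12)
  # all singletons: -gamma * sum k_i^2 / 2m
  k <- rowSums(g2)
  expect_equal(modularity_score(g2, 1:8, gamma = 1.3),
               -1.3 * sum(k^2) / sum(g2), tolerance = 1e-12)
  # two-clique partition against the brute-force double sum
  memb <- rep(1:2, each = 4)
  expect_equal(modularity_score(g2, memb, gamma = 1),
               oracle_modularity(g2, memb, 1), tolerance = 1e-12)
  # random weighted graphs, random partitions
  for (s in 1:10) {
    a <- random_weighted_graph(9, 0.5, s)
    if (sum(a) == 0) next
    set.seed(s); memb <- sample(1:3, 9, replace = TRUE)
    gamma <- runif(1, 0.5, 2)
    expect_equal(modularity_score(a, memb, gamma),
                 oracle_modularity(a, memb, gamma), tolerance = 1e-10)
  }
  # relabeling invariance
  a <- random_weighted_graph(9, 0.5, 3)
  memb <- c(1, 1, 2, 2, 3, 3, 1, 2, 3)
  relab <- c(3, 3, 1, 1, 2, 2, 3, 1, 2)
  expect_equal(modularity_score(a, memb, 1), modularity_score(a, relab, 1))
  expect_error(modularity_score(matrix(0, 3, 3), c(1, 1, 1)),
               class = "fvconn_invalid_state")
})

test_that("Louvain finds planted cliques and dissolves at high resolution", {
  ari <- mclust::adjustedRandIndex
  two_k5 <- matrix(0, 10, 10)
  two_k5[1:5, 1:5] <- 1; two_k5[6:10, 6:10] <- 1; diag(two_k5) <- 0
  truth <- rep(1:2, each = 5)
  for (s in 1:20) {
    p <- optimize_partition(two_k5, gamma = 1, seed = s, n_restarts = 2)
    expect_equal(ari(p$membership, truth), 1)
  }
  # Q never below the one-module partition
  expect_gte(optimize_partition(two_k5, gamma = 1, seed = 1)$Q,
             modularity_score(two_k5, rep(1, 10), 1))
  # very large gamma: all singletons
  p <- optimize_partition(two_k5, gamma = 50, seed = 1, n_restarts = 2)
  expect_equal(length(unique(p$membership)), 10)
})

test_that("Louvain recovers a planted two-block SBM", {
  ari <- mclust::adjustedRandIndex
  hits <- 0
  truth <- rep(1:2, each = 20)
  for (s in 1:30) {
    set.seed(s)
    a <- matrix(0, 40, 40)
    ut <- upper.tri(a)
    pm <- ifelse(outer(truth, truth, "==")[ut], 0.5, 0.05)
    a[ut] <- as.numeric(runif(sum(ut)) < pm)
    a <- a + t(a)
    p <- optimize_partition(a, gamma = 1, seed = s, n_restarts = 5)
    if (ari(p$membership, truth) == 1) hits <- hits + 1
  }
  expect_gte(hits, 28)  # >= 95% recovery rate
})

test_that("consensus coassignment is exact for unambiguous structure", {
  two_k5 <- matrix(0, 10, 10)
  two_k5[1:5, 1:5] <- 1; two_k5[6:10, 6:10] <- 1; diag(two_k5) <- 0
  cons <- multiresolution_consensus(two_k5,
                                    gamma_grid = c(0.5, 1, 1.5, 2),
                                    n_samples_per_gamma = 5, seed = 1)
  co <- cons$coassignment
  within <- c(co[1:5, 1:5][upper.tri(matrix(0, 5, 5))],
              co[6:10, 6:10][upper.tri(matrix(0, 5, 5))])
  expect_equal(within, rep(1, length(within)))
  expect_equal(max(co[1:5, 6:10]), 0)
  expect_equal(length(unique(cons$assignment)), 2)
  # proper frequencies: every entry is m / n_samples
  expect_true(all(abs(co * ncol(cons$partitions) -
                        round(co * ncol(cons$partitions))) < 1e-12))
  # idempotence: consensus on the consensus assignment reproduces itself
  ari <- mclust::adjustedRandIndex
  expect_equal(ari(cons$assignment, rep(1:2, each = 5)), 1)
})

test_that("consensus finds nothing to split where no partition is consistent", {
  # a complete graph admits no consistent sub-partition at any resolution:
  # the hierarchy stays a single module
  k <- matrix(1, 30, 30); diag(k) <- 0
  cons <- multiresolution_consensus(k, gamma_grid = seq(0.5, 1.5, length.out = 10),
                                    n_samples_per_gamma = 4, seed = 1)
  expect_equal(length(unique(cons$assignment)), 1)
})

test_that("edge rewiring destroys recoverable planted structure", {
  # degree-preserving rewiring of a two-block graph: the consensus modules
  # carry no information about the pre-rewiring blocks (any modules found
  # are chance communities of the realized random graph)
  ari <- mclust::adjustedRandIndex
  two <- matrix(0, 40, 40)
  two[1:20, 1:20] <- 1; two[21:40, 21:40] <- 1; diag(two) <- 0
  rw <- rewire_degree_preserving(two, n_swaps_per_edge = 20, seed = 3)
  cons <- multiresolution_consensus(rw, gamma_grid = seq(0.5, 2, length.out = 10),
                                    n_samples_per_gamma = 4, seed = 4)
  expect_lt(abs(ari(cons$assignment, rep(1:2, each = 20))), 0.1)
})

test_that("consensus recovers the planted six-module architecture", {
  ari <- mclust::adjustedRandIndex
  parc <- generate_parcellation(92, 6, seed = 11)
  cts <- generate_structural_counts(parc, seed = 11)
  cons <- multiresolution_consensus(structural_matrix(cts)$weighted, seed = 11)
  expect_equal(length(unique(cons$assignment)), 6)
  expect_gte(ari(cons$assignment, parc$module), 0.9)
})
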