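test_that("density matches exhaustive pair counting, globally and by block", {
  k6 <- matrix(1, 6, 6); diag(k6) <- 0
  parc6 <- toy_parcellation(3)
  d <- network_density(conn_matrix(k6, weighted = FALSE), parc6)
  expect_equal(d$global, 1)
  expect_equal(d$intra_L, 1)
  expect_equal(d$inter, 1)
  e0 <- network_density(conn_matrix(matrix(0, 6, 6), weighted = FALSE), parc6)
  expect_equal(e0$global, 0)

  for (s in 1:20) {
    a <- random_binary_graph(8, 0.4, s)
    parc <- toy_parcellation(4)
    got <- network_density(a, parc)
    want <- oracle_density_blocks(a, parc$hemisphere)
    expect_equal(got$global, want$global)
    expect_equal(got$intra_L, want$intra_L)
    expect_equal(got$intra_R, want$intra_R)
    expect_equal(got$inter, want$inter)
    # block decomposition of the edge count
    expect_equal(got$n_edges, got$edges_L + got$edges_R + got$edges_inter)
  }
})

test_that("degree and its cCDF follow the inclusive convention", {
  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star[2:6, 1] <- 1
  dc <- degree_ccdf(star)
  expect_equal(unname(dc$degree), c(5L, rep(1L, 5)))
  expect_equal(dc$ccdf$ccdf[dc$ccdf$k == 0], 1)
  expect_true(all(diff(dc$ccdf$ccdf) <= 0))
  # sorted-count oracle on a random graph
  a <- random_binary_graph(15, 0.3, 7)
  dc <- degree_ccdf(a)
  k <- rowSums(a)
  for (kk in dc$ccdf$k)
    expect_equal(dc$ccdf$ccdf[dc$ccdf$k == kk], mean(k >= kk))
})

test_that("clustering coefficient equals brute-force triangle enumeration", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_coefficient(tri)$per_node), rep(1, 3))
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(clustering_coefficient(p3)$mean, 0)
  a <- random_binary_graph(12, 0.4, 42)
  expect_equal(unname(clustering_coefficient(a)$per_node), oracle_clustering(a),
               tolerance = 1e-12)
})

test_that("characteristic path length excludes unreachable pairs", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(characteristic_path_length(k5)$L, 1)
  p4 <- matrix(0, 4, 4)
  for (i in 1:3) p4[i, i + 1] <- p4[i + 1, i] <- 1
  expect_equal(characteristic_path_length(p4)$L, 10 / 6)
  # disconnected graph: unreachable pairs reported, finite mean
  two <- matrix(0, 4, 4); two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  res <- characteristic_path_length(two)
  expect_equal(res$L, 1)
  expect_equal(res$n_unreachable_pairs, 8)
  expect_equal(res$n_components, 2)
  # edgeless: sentinel
  expect_true(is.na(characteristic_path_length(matrix(0, 3, 3))$L))
})

test_that("rewiring preserves the degree sequence and lowers lattice clustering", {
  ring <- matrix(0, 50, 50)
  for (i in 1:50) for (off in 1:3) {
    j <- ((i + off - 1) %% 50) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  expect_equal(clustering_coefficient(ring)$mean, 0.6, tolerance = 1e-12)
  drops <- vapply(1:20, function(s) {
    rw <- rewire_degree_preserving(ring, n_swaps_per_edge = 10, seed = s)
    expect_equal(sort(rowSums(rw)), sort(rowSums(ring)))
    expect_equal(sum(rw), sum(ring))
    clustering_coefficient(rw)$mean
  }, numeric(1))
  expect_true(all(drops < 0.6))
})

test_that("edge distances use Euclidean geometry and hemisphere flags", {
  parc <- toy_parcellation(1)
  parc$x_mm <- c(-3, 0); parc$y_mm <- c(0, 4); parc$z_mm <- c(0, 0)
  a <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(parc$region_id, parc$region_id))
  prof <- edge_distance_profile(conn_matrix(a, weighted = FALSE), parc)
  expect_equal(prof$edges$distance_mm, 5)  # 3-4-5 triangle
  expect_true(prof$edges$interhemispheric)

  parc2 <- generate_parcellation(6, 2, seed = 2)
  cts <- generate_structural_counts(parc2, seed = 2)
  sm <- structural_matrix(cts)
  prof2 <- edge_distance_profile(sm$weighted, parc2)
  homo <- prof2$edges[substr(prof2$edges$from, 1, 6) ==
                      substr(prof2$edges$to, 1, 6), ]
  expect_true(all(homo$interhemispheric))
})

test_that("measures are relabeling invariant", {
  a <- random_binary_graph(10, 0.35, 5)
  perm <- sample(10)
  ap <- a[perm, perm]
  expect_equal(sort(unname(clustering_coefficient(a)$per_node)),
               sort(unname(clustering_coefficient(ap)$per_node)))
  expect_equal(characteristic_path_length(a)$L, characteristic_path_length(ap)$L)
  expect_equal(network_density(a)$global, network_density(ap)$global)
})
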