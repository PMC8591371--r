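test_that("generate_parcellation builds mirrored bilateral parcellations", {
  parc <- generate_parcellation(92, 6, seed = 1)
  expect_equal(nrow(parc), 184)
  expect_equal(sum(parc$hemisphere == "L"), 92)
  expect_equal(sum(parc$hemisphere == "R"), 92)
  expect_false(anyDuplicated(parc$region_id) > 0)
  # mirror: left x is the negated right x, other coordinates equal
  l <- parc[parc$hemisphere == "L", ]
  r <- parc[parc$hemisphere == "R", ]
  expect_equal(l$x_mm, -r$x_mm)
  expect_equal(l$y_mm, r$y_mm)
  expect_equal(l$module, r$module)

  tiny <- generate_parcellation(1, 1, seed = 0)
  expect_equal(nrow(tiny), 2)
  expect_equal(unique(tiny$module), 1L)

  expect_error(generate_parcellation(0, 1), class = "fvconn_invalid_argument")
  expect_error(generate_parcellation(3, 5), class = "fvconn_invalid_argument")
})

test_that("planted modules are spatially contiguous", {
  parc <- generate_parcellation(10, 2, seed = 7)
  d <- region_distances(parc)
  same <- outer(parc$module, parc$module, "==")
  hemi_same <- outer(parc$hemisphere, parc$hemisphere, "==")
  ut <- upper.tri(d)
  within <- mean(d[ut & same & hemi_same])
  between <- mean(d[ut & !same & hemi_same])
  expect_lt(within, between)
})

test_that("structural counts decay with distance and respect the module gain", {
  # zero-distance same-hemisphere pair: expectation is base * gain exactly
  parc <- toy_parcellation(2)
  parc$x_mm[parc$hemisphere == "R"] <- 10
  parc$y_mm <- 0
  draws <- vapply(1:25, function(s)
    generate_structural_counts(parc, base_count = 1000, within_module_gain = 20,
                               seed = s)[3, 4], numeric(1))
  expect_equal(mean(draws), 1000 * 20, tolerance = 0.02)

  expect_error(generate_structural_counts(parc, lambda_mm = 0),
               class = "fvconn_invalid_argument")
  cts <- generate_structural_counts(parc, seed = 1)
  expect_true(isSymmetric(cts))
  expect_true(all(diag(cts) == 0))
})

test_that("penalty-free flat-decay limit equalizes intra and inter counts", {
  parc <- generate_parcellation(10, 2, seed = 3)
  inter <- outer(parc$hemisphere, parc$hemisphere, "!=")
  ut <- upper.tri(inter)
  intra_m <- inter_m <- numeric(40)
  for (s in 1:40) {
    cts <- generate_structural_counts(parc, lambda_mm = 1e9,
                                      interhemi_penalty = 1,
                                      within_module_gain = 1, seed = s)
    intra_m[s] <- mean(cts[ut & !inter])
    inter_m[s] <- mean(cts[ut & inter])
  }
  expect_equal(mean(intra_m), mean(inter_m), tolerance = 0.02)
})

test_that("interhemispheric penalty lowers binarized interhemispheric density", {
  wins <- 0
  for (s in 1:100) {
    parc <- generate_parcellation(46, 6, seed = s)
    cts <- generate_structural_counts(parc, interhemi_penalty = 0.2, seed = s)
    dens <- network_density(structural_matrix(cts)$binary, parc)
    intra <- mean(c(dens$intra_L, dens$intra_R))
    if (intra > dens$inter) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("intrahemispheric counts decay monotonically in binned distance", {
  ok <- 0
  for (s in 1:100) {
    parc <- generate_parcellation(12, 3, seed = s)
    cts <- generate_structural_counts(parc, seed = s)
    d <- region_distances(parc)
    same_h <- outer(parc$hemisphere, parc$hemisphere, "==")
    ut <- upper.tri(d) & same_h
    bins <- cut(d[ut], breaks = quantile(d[ut], 0:4 / 4), include.lowest = TRUE)
    means <- tapply(cts[ut], bins, mean)
    if (all(diff(means) <= 0)) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("hemisphere swap leaves the count distribution invariant in expectation", {
  parc <- generate_parcellation(8, 2, seed = 5)
  nl <- sum(parc$hemisphere == "L")
  tot_l <- tot_r <- 0
  for (s in 1:40) {
    cts <- generate_structural_counts(parc, seed = s)
    bl <- cts[1:nl, 1:nl]
    br <- cts[(nl + 1):(2 * nl), (nl + 1):(2 * nl)]
    tot_l <- tot_l + mean(bl[upper.tri(bl)])
    tot_r <- tot_r + mean(br[upper.tri(br)])
  }
  expect_equal(tot_l / 40, tot_r / 40, tolerance = 0.03)
})

test_that("generate_bold hits run length and correlation targets", {
  parc <- generate_parcellation(10, 2, seed = 1)
  design <- run_design(duration = 300, tr = 1.5)
  rs <- generate_bold(parc, design, seed = 1)
  expect_equal(nrow(rs$data), 200)
  expect_identical(colnames(rs$data), parc$region_id)

  # strong within-module coupling shows up in sample correlations
  truth <- planted_truth(parc, coupling_within = 0.6, coupling_between = 0.1)
  diffs <- vapply(1:10, function(s) {
    rs <- generate_bold(parc, design, truth,
                        epochs = data.frame(label = character(),
                                            onset_s = numeric(),
                                            offset_s = numeric()),
                        stim_amplitude = 0, seed = s)
    cc <- cor(rs$data)
    same <- outer(parc$module, parc$module, "==")
    ut <- upper.tri(cc)
    mean(cc[ut & same]) - mean(cc[ut & !same])
  }, numeric(1))
  expect_gte(mean(diffs), 0.3)

  expect_error(generate_bold(parc, design, noise_sd = -1),
               class = "fvconn_invalid_argument")
})

test_that("uncoupled regions are near-independent at the null", {
  parc <- generate_parcellation(10, 2, seed = 1)
  design <- run_design()
  truth <- planted_truth(parc, coupling_within = 0, coupling_between = 0,
                         hub_gain = 0)
  m <- vapply(1:50, function(s) {
    rs <- generate_bold(parc, design, truth, seed = s)
    cc <- cor(rs$data)
    mean(abs(cc[upper.tri(cc)]))
  }, numeric(1))
  expect_lt(mean(m), 0.1)
})
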