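test_that("MTD identities: self-coupling 1, anti-phase -1, 18 s window", {
  set.seed(41)
  x <- matrix(rnorm(400), 200, 2)
  x[, 2] <- -x[, 1]
  tens <- mtd(x, w = 12, tr = 1.5)
  # full-run mean of the self-pair is exactly 1 (population-sd normalization)
  d <- diff(x); d <- sweep(d, 2, colMeans(d))
  z <- sweep(d, 2, sqrt(colMeans(d^2)), "/")
  expect_equal(mean(z[, 1]^2), 1, tolerance = 1e-10)
  expect_equal(mean(z[, 1] * z[, 2]), -1, tolerance = 1e-10)
  # window span in seconds
  expect_equal(tens$w * tens$tr, 18)
  expect_equal(dim(tens$values)[1], 199 - 12 + 1)
})

test_that("MTD equals the naive double-loop oracle", {
  set.seed(42)
  x <- matrix(rnorm(80 * 5), 80, 5)
  tens <- mtd(x, w = 7, tr = 2)
  for (k in c(1, 20, 50, 73)) for (i in 1:4) for (j in (i + 1):5)
    expect_equal(tens$values[k, i, j], oracle_mtd_pair(x, i, j, 7, k),
                 tolerance = 1e-12)
  # symmetric slices
  expect_equal(tens$values[20, , ], t(tens$values[20, , ]), tolerance = 1e-12)
})

test_that("MTD is invariant to per-region affine rescaling", {
  set.seed(43)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- sweep(sweep(x, 2, c(2, 5, 0.3), "*"), 2, c(10, -4, 100), "+")
  a <- mtd(x, w = 5, tr = 1)
  b <- mtd(y, w = 5, tr = 1)
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("epoch averaging pools the right windows", {
  set.seed(44)
  x <- matrix(rnorm(100 * 4), 100, 4)
  tens <- mtd(x, w = 6, tr = 1)
  # single-window epoch equals that slice exactly
  ct <- tens$window_times[10]
  ep1 <- data.frame(label = "one", onset_s = ct - 0.4, offset_s = ct + 0.4)
  st <- epoch_average(tens, ep1)
  expect_equal(st$one$matrix, tens$values[10, , ])
  expect_equal(st$one$n_windows, 1L)
  # same-label epochs pool; two identical slices average to themselves
  ep2 <- data.frame(label = c("a", "a"),
                    onset_s = c(ct - 0.4, ct - 0.4 + 1e-9),
                    offset_s = c(ct + 0.4, ct + 0.4))
  st2 <- epoch_average(tens, ep2)
  expect_equal(st2$a$matrix, tens$values[10, , ])
  # oracle: mean of raw slices with centers inside the epoch
  ep3 <- data.frame(label = "b", onset_s = 20, offset_s = 40)
  sel <- tens$window_times >= 20 & tens$window_times < 40
  st3 <- epoch_average(tens, ep3)
  expect_equal(st3$b$matrix, apply(tens$values[sel, , ], c(2, 3), mean))
  # an epoch with no window centers errors with its name
  expect_error(epoch_average(tens, data.frame(label = "late", onset_s = 99,
                                              offset_s = 99.5)),
               "late")
})

test_that("windowed centrality reduces to static EC and is flat when constant", {
  # constant coupling structure: identical slices -> flat traces
  set.seed(45)
  base <- random_weighted_graph(6, 0.8, 1) + 0.05
  diag(base) <- 0
  tens <- structure(list(values = aperm(array(base, c(6, 6, 8)), c(3, 1, 2)),
                         w = 3L, tr = 1, window_times = 1:8,
                         zero_variance_regions = character(0)),
                    class = "fv_mtd")
  tr <- windowed_centrality(tens)
  expect_lt(max(apply(tr, 1, sd)), 1e-6)
  # single-window tensor equals static EC of the slice
  tens1 <- structure(list(values = array(base, c(1, 6, 6)), w = 3L, tr = 1,
                          window_times = 1, zero_variance_regions = character(0)),
                     class = "fv_mtd")
  tr1 <- windowed_centrality(tens1)
  expect_equal(unname(tr1[, 1]), unname(eigenvector_centrality(base)$ec),
               tolerance = 1e-10)
})

test_that("state comparison computes Jaccard overlap and poly-functional sets", {
  set.seed(46)
  m1 <- random_weighted_graph(12, 0.6, 2)
  m1[2, ] <- m1[2, ] + 0.9 * (1:12 != 2); m1[, 2] <- m1[2, ]
  st <- function(m, lab) structure(list(label = lab, matrix = m, n_windows = 5),
                                   class = "fv_epoch_state")
  same <- state_hub_comparison(list(a = st(m1, "a"), b = st(m1, "b")))
  expect_equal(unname(same$jaccard["a", "b"]), 1)
  # disjoint hubs: zero overlap, nothing poly-functional
  m2 <- random_weighted_graph(12, 0.6, 3)
  m2[7, ] <- m2[7, ] + 0.9 * (1:12 != 7); m2[, 7] <- m2[7, ]
  diff <- state_hub_comparison(list(a = st(m1, "a"), b = st(m2, "b")),
                               z_cutoff = 2)
  if (length(diff$hubs$a) && length(diff$hubs$b)) {
    expect_equal(unname(diff$jaccard["a", "b"]), 0)
    expect_length(diff$poly_functional, 0)
  }
  expect_error(state_hub_comparison(list(st(m1, "a"))),
               class = "fvconn_invalid_argument")
})

test_that("planted epoch coupling is recovered in the epoch state", {
  sess <- simulate_hub_session(seed = 5, n_per_hemi = 10, n_modules = 3,
                               n_reps = 1)
  lab <- sess$labels[2]
  hubs <- sess$hubs[[lab]]
  own <- abs(sess$states[[lab]]$matrix[hubs[1], hubs[2]])
  others <- vapply(setdiff(sess$labels, lab), function(l)
    abs(sess$states[[l]]$matrix[hubs[2], hubs[1]]), numeric(1))
  expect_gt(own, max(others))
})
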