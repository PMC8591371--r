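# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (and igraph): plain loops and textbook formulas only.

# symmetric 0/1 adjacency of an Erdos-Renyi draw
random_binary_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < p)
  a + t(a)
}

random_weighted_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  w <- runif(sum(ut)) * (runif(sum(ut)) < p)
  a[ut] <- w
  a + t(a)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t <- 0
    for (u in nb) for (v in nb) if (u < v && a[u, v] == 1) t <- t + 1
    t / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

oracle_path_length <- function(a) {
  d <- oracle_floyd_warshall(a)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_density_blocks <- function(a, hemi) {
  n <- nrow(a)
  blocks <- list(global = 0, intra_L = 0, intra_R = 0, inter = 0)
  tots <- list(global = 0, intra_L = 0, intra_R = 0, inter = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    key <- if (hemi[i] != hemi[j]) "inter"
           else if (hemi[i] == "L") "intra_L" else "intra_R"
    for (k in c("global", key)) {
      blocks[[k]] <- blocks[[k]] + a[i, j]
      tots[[k]] <- tots[[k]] + 1
    }
  }
  lapply(setNames(names(blocks), names(blocks)),
         function(k) blocks[[k]] / tots[[k]])
}

oracle_modularity <- function(a, g, gamma) {
  n <- nrow(a)
  k <- rowSums(a)
  m2 <- sum(a)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (g[i] == g[j]) q <- q + a[i, j] - gamma * k[i] * k[j] / m2
  q
}

oracle_eigencentrality <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / sum(v)
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# BH step-up by direct enumeration of the definition
oracle_bh_survivors <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(integer(0))
  sort(ord[seq_len(max(ok))])
}

# naive MTD: loops straight from the printed formula, centred derivatives
oracle_mtd_pair <- function(x, i, j, w, t0) {
  d <- diff(x)
  d <- sweep(d, 2, colMeans(d))
  sig <- sqrt(colMeans(d^2))
  mean(d[t0:(t0 + w - 1), i] * d[t0:(t0 + w - 1), j]) / (sig[i] * sig[j])
}

oracle_dft_amplitude <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  ks <- seq_len(floor(n / 2))
  vapply(ks, function(k) {
    t <- 0:(n - 1)
    Mod(sum(x * exp(-2i * pi * k * t / n)))
  }, numeric(1))
}

# tiny bilateral parcellation with hand-set coordinates, for measure tests
toy_parcellation <- function(n_per_hemi = 3) {
  ids <- sprintf("r%02d", seq_len(n_per_hemi))
  right <- data.frame(region_id = paste0(ids, "_R"), hemisphere = "R",
                      x_mm = seq_len(n_per_hemi) * 5,
                      y_mm = seq_len(n_per_hemi) * 2,
                      z_mm = rep(0, n_per_hemi),
                      module = rep(1L, n_per_hemi),
                      stringsAsFactors = FALSE)
  left <- right
  left$region_id <- paste0(ids, "_L")
  left$hemisphere <- "L"
  left$x_mm <- -right$x_mm
  parc <- rbind(left, right)
  class(parc) <- c("fv_parcellation", "data.frame")
  parc
}

# planted 4-epoch hub runs matching the study's session (two scan
# repetitions averaged), reused by dynamics tests and the acceptance suite
simulate_hub_session <- function(seed, n_per_hemi = 30, n_modules = 6,
                                 n_reps = 2) {
  parc <- generate_parcellation(n_per_hemi, n_modules, seed = seed)
  design <- run_design()
  epochs <- default_epochs(design)
  labs <- epochs$label
  shared <- parc$region_id[2]
  uniq <- parc$region_id[4 + 3 * seq_along(labs)]
  hubs <- setNames(lapply(seq_along(labs), function(i) c(shared, uniq[i])), labs)
  truth <- planted_truth(parc, epoch_hubs = hubs)
  states <- NULL
  for (r in seq_len(n_reps)) {
    rs <- generate_bold(parc, design, truth, epochs, seed = seed * 100 + r)
    st <- epoch_average(mtd(rs, w = 12), epochs)
    if (is.null(states)) states <- st
    else for (l in labs) states[[l]]$matrix <- states[[l]]$matrix + st[[l]]$matrix
  }
  for (l in labs) states[[l]]$matrix <- states[[l]]$matrix / n_reps
  list(parc = parc, epochs = epochs, labels = labs, shared = shared,
       unique = uniq, hubs = hubs, states = states)
}
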