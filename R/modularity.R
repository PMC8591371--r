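# Modularity and multiresolution consensus community detection.
# The quality function follows the study's printed form
#   Q(gamma, {g_i}) = sum_ij [A_ij - gamma * P_ij] delta(g_i, g_j)
# with the Newman-Girvan configuration null P_ij = k_i k_j / (2m) and no
# global 1/(2m) normalization; a normalized variant is exposed for
# comparison with standard toolboxes.

#' Modularity of a partition
#'
#' @param conn `fv_conn` or matrix (weighted or binary, non-negative).
#' @param membership integer vector of module labels per node.
#' @param gamma resolution parameter.
#' @param normalized divide by 2m (standard Newman convention).
#' @return scalar Q.
#' @export
modularity_score <- function(conn, membership, gamma = 1, normalized = FALSE) {
  a <- conn_values(conn)
  if (length(membership) != nrow(a))
    stop_invalid("membership must cover all nodes")
  m2 <- sum(a)
  if (m2 == 0) stop_state("modularity undefined for an edgeless graph")
  k <- rowSums(a)
  same <- outer(membership, membership, "==")
  q <- sum((a - gamma * outer(k, k) / m2)[same])
  if (normalized) q / m2 else q
}

# Contiguous labels 1..C, first appearance order.
relabel <- function(g) as.integer(factor(g, levels = unique(g)))

#' Louvain maximization of modularity at resolution gamma
#'
#' Best-of-`n_restarts` Louvain runs; each restart permutes the node order
#' (community detection is order-sensitive) and the best partition by
#' [modularity_score()] is returned. The result never scores below the
#' trivial one-module partition.
#'
#' @inheritParams modularity_score
#' @param seed integer seed.
#' @param n_restarts number of restarts.
#' @return list of class `fv_partition`: `membership` (contiguous labels
#'   from 1), `gamma`, `Q` (unnormalized), `Q_normalized`.
#' @export
optimize_partition <- function(conn, gamma = 1, seed = 1L, n_restarts = 10) {
  a <- conn_values(conn)
  n <- nrow(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  set.seed(as.integer(seed))
  best <- rep(1L, n)
  best_q <- modularity_score(a, best, gamma)
  for (r in seq_len(n_restarts)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, resolution = gamma)
    # original vertex i sits at position perm[i] in the permuted graph
    memb <- as.integer(igraph::membership(cl))[perm]
    q <- modularity_score(a, memb, gamma)
    if (q > best_q) {
      best <- memb
      best_q <- q
    }
  }
  structure(list(membership = relabel(best), gamma = gamma, Q = best_q,
                 Q_normalized = best_q / sum(a)),
            class = "fv_partition")
}

# Coassignment matrix of a set of partitions (columns of a matrix).
coassignment_matrix <- function(parts) {
  n <- nrow(parts)
  acc <- matrix(0L, n, n)
  for (j in seq_len(ncol(parts)))
    acc <- acc + outer(parts[, j], parts[, j], "==")
  acc / ncol(parts)
}

#' Multiresolution consensus modularity
#'
#' Samples partitions across a resolution sweep, accumulates the
#' co-assignment frequency matrix, and extracts a hierarchy by recursive
#' clustering of the significant co-assignments. Significance is a
#' family-wise permutation null: each sampled partition's labels are
#' permuted over nodes, and the threshold `alpha` is the 95th percentile of
#' the per-permutation maximum off-diagonal null co-assignment — so a graph
#' with no consistent structure collapses to a single module.
#'
#' @param conn `fv_conn` or non-negative matrix.
#' @param gamma_grid resolutions to sweep (default 40 log-spaced in
#'   `[0.5, 2]`).
#' @param n_samples_per_gamma Louvain samples per resolution.
#' @param seed integer seed.
#' @param n_null_perm permutation rounds for the null threshold.
#' @return list of class `fv_consensus`: `assignment` (final module labels),
#'   `coassignment`, `hierarchy` (nested list of region index sets),
#'   `alpha`, `gamma_grid`, `partitions` (N x samples matrix).
#' @export
multiresolution_consensus <- function(conn,
                                      gamma_grid = exp(seq(log(0.5), log(2),
                                                           length.out = 40)),
                                      n_samples_per_gamma = 5,
                                      seed = 1L, n_null_perm = 50) {
  if (!length(gamma_grid)) stop_invalid("gamma_grid must be non-empty")
  a <- conn_values(conn)
  n <- nrow(a)
  set.seed(as.integer(seed))

  parts <- matrix(NA_integer_, n,
                  length(gamma_grid) * n_samples_per_gamma)
  s <- 0L
  for (gam in gamma_grid) {
    for (i in seq_len(n_samples_per_gamma)) {
      s <- s + 1L
      p <- optimize_partition(a, gamma = gam,
                              seed = child_seed(seed, s), n_restarts = 1)
      parts[, s] <- p$membership
    }
  }
  co <- coassignment_matrix(parts)
  dimnames(co) <- dimnames(a)

  # Family-wise permutation null on the coassignment scale.
  null_max <- numeric(n_null_perm)
  for (r in seq_len(n_null_perm)) {
    acc <- matrix(0L, n, n)
    for (j in seq_len(ncol(parts))) {
      pj <- parts[sample.int(n), j]
      acc <- acc + outer(pj, pj, "==")
    }
    nc <- acc / ncol(parts)
    null_max[r] <- max(nc[upper.tri(nc)])
  }
  alpha <- as.numeric(quantile(null_max, 0.95, type = 7))

  cluster_sub <- function(idx) {
    co_sub <- co[idx, idx, drop = FALSE]
    if (length(idx) < 2 || max(co_sub[upper.tri(co_sub)]) <= alpha)
      return(list(members = idx))  # nothing significant: leaf
    keep <- co_sub > alpha
    diag(keep) <- FALSE
    w <- co_sub * keep
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    memb <- igraph::membership(igraph::cluster_louvain(g))
    if (length(unique(memb)) == 1) return(list(members = idx))
    children <- lapply(split(idx, memb), cluster_sub)
    list(members = idx, children = unname(children))
  }
  hierarchy <- cluster_sub(seq_len(n))

  assignment <- integer(n)
  lab <- 0L
  walk <- function(node) {
    if (is.null(node$children)) {
      lab <<- lab + 1L
      assignment[node$members] <<- lab
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(hierarchy)
  names(assignment) <- rownames(a)

  structure(list(assignment = assignment, coassignment = co,
                 hierarchy = hierarchy, alpha = alpha,
                 gamma_grid = gamma_grid,
                 n_samples_per_gamma = n_samples_per_gamma,
                 partitions = parts),
            class = "fv_consensus")
}

#' @export
print.fv_consensus <- function(x, ...) {
  cat(sprintf("<fv_consensus> %d nodes, %d modules (alpha = %.3f, %d samples)\n",
              length(x$assignment), length(unique(x$assignment)), x$alpha,
              ncol(x$partitions)))
  invisible(x)
}
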