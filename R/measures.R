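# Static graph characterization of binary networks: density by hemisphere
# block, degree + cCDF, Watts-Strogatz clustering, characteristic path
# length, degree-preserving rewired nulls, and edge-distance profiles.

assert_binary <- function(a) {
  if (!all(a %in% c(0, 1))) stop_invalid("expected a binary (0/1) matrix")
  a
}

#' Network density, globally and by hemisphere block
#'
#' Global density rho = 2E / (N(N-1)); intrahemispheric densities are
#' computed on each hemisphere's submatrix and the interhemispheric density
#' is the cross-block edge count over N_L * N_R.
#'
#' @param conn binary `fv_conn` (or 0/1 matrix).
#' @param parcellation an `fv_parcellation` matching the matrix order;
#'   `NULL` gives the global density only.
#' @return list with `global`, `intra_L`, `intra_R`, `inter` and edge counts.
#' @export
network_density <- function(conn, parcellation = NULL) {
  a <- assert_binary(conn_values(conn))
  n <- nrow(a)
  if (n < 2) stop_invalid("need at least 2 nodes")
  e_tot <- sum(a[upper.tri(a)])
  out <- list(global = e_tot / (n * (n - 1) / 2), n_edges = e_tot)
  if (!is.null(parcellation)) {
    stopifnot(nrow(parcellation) == n)
    for (h in c("L", "R")) {
      idx <- parcellation$hemisphere == h
      sub <- a[idx, idx, drop = FALSE]
      m <- sum(idx)
      out[[paste0("intra_", h)]] <-
        if (m >= 2) sum(sub[upper.tri(sub)]) / (m * (m - 1) / 2) else NA_real_
      out[[paste0("edges_", h)]] <- sum(sub[upper.tri(sub)])
    }
    il <- parcellation$hemisphere == "L"
    cross <- a[il, !il, drop = FALSE]
    out$inter <- sum(cross) / (sum(il) * sum(!il))
    out$edges_inter <- sum(cross)
  }
  out
}

#' Node degree and its complementary CDF
#'
#' `ccdf(k)` = fraction of nodes with degree >= k (inclusive), so
#' `ccdf(0) = 1` and the function is non-increasing.
#'
#' @param conn binary `fv_conn` or 0/1 matrix.
#' @return list with `degree` (named integer vector) and `ccdf`
#'   (data.frame k, ccdf).
#' @export
degree_ccdf <- function(conn) {
  a <- assert_binary(conn_values(conn))
  k <- as.integer(rowSums(a))
  names(k) <- rownames(a)
  ks <- 0:max(k, 0L)
  ccdf <- vapply(ks, function(kk) mean(k >= kk), numeric(1))
  list(degree = k, ccdf = data.frame(k = ks, ccdf = ccdf))
}

#' Watts-Strogatz local clustering coefficient
#'
#' `C_i = triangles_i / (k_i (k_i - 1) / 2)`; nodes with degree < 2 get
#' `C_i = 0` and are included in the mean.
#'
#' @param conn binary `fv_conn` or 0/1 matrix with zero diagonal.
#' @return list with `per_node` (named vector) and `mean`.
#' @export
clustering_coefficient <- function(conn) {
  a <- assert_binary(conn_values(conn))
  if (any(diag(a) != 0)) stop_invalid("diagonal must be zero")
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  c_i <- ifelse(k >= 2, tri / (k * (k - 1) / 2), 0)
  names(c_i) <- rownames(a)
  list(per_node = c_i, mean = mean(c_i))
}

#' Characteristic path length
#'
#' Mean breadth-first shortest-path length over all ordered pairs of
#' distinct nodes that are reachable from one another; unreachable pairs
#' are excluded from the mean and reported separately. An edgeless graph
#' returns `L = NA`.
#'
#' @param conn binary `fv_conn` or 0/1 matrix.
#' @return list with `L`, `n_unreachable_pairs` (ordered pairs),
#'   `n_components`.
#' @export
characteristic_path_length <- function(conn) {
  a <- assert_binary(conn_values(conn))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  list(
    L = if (any(reach)) mean(off[reach]) else NA_real_,
    n_unreachable_pairs = sum(!reach),
    n_components = igraph::count_components(g)
  )
}

#' Degree-preserving rewired null network
#'
#' Maslov-Sneppen double-edge swaps: the degree sequence is preserved
#' exactly and no self-loops or multi-edges are introduced. Used as the
#' null model against which empirical clustering is judged.
#'
#' @param conn binary `fv_conn` or 0/1 matrix.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return binary matrix (same dimnames), attribute `n_swaps_attempted`.
#' @export
rewire_degree_preserving <- function(conn, n_swaps_per_edge = 10, seed = 1L) {
  a <- assert_binary(conn_values(conn))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  ne <- igraph::ecount(g)
  if (ne < 2) stop_invalid("need at least 2 edges to rewire")
  set.seed(as.integer(seed))
  niter <- n_swaps_per_edge * ne
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
  out <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  dimnames(out) <- dimnames(a)
  attr(out, "n_swaps_attempted") <- niter
  out
}

#' Edge-distance profile
#'
#' One row per surviving edge: Euclidean distance between region centers,
#' edge weight, and whether the edge crosses hemispheres; plus binned mean
#' weights by distance, split intra/inter, for the weight-vs-distance
#' analyses.
#'
#' @param conn `fv_conn` (weighted or binary).
#' @param parcellation an `fv_parcellation` with coordinates for all regions.
#' @param n_bins number of equal-width distance bins.
#' @return list with `edges` (data.frame) and `binned` (data.frame).
#' @export
edge_distance_profile <- function(conn, parcellation, n_bins = 10) {
  a <- conn_values(conn)
  if (nrow(parcellation) != nrow(a))
    stop_state("parcellation does not match the matrix")
  if (any(!is.finite(as.matrix(parcellation[, c("x_mm", "y_mm", "z_mm")])))) {
    bad <- parcellation$region_id[
      !stats::complete.cases(parcellation[, c("x_mm", "y_mm", "z_mm")])]
    stop_state("missing coordinates for region(s): ", paste(bad, collapse = ", "))
  }
  d <- region_distances(parcellation)
  inter <- outer(parcellation$hemisphere, parcellation$hemisphere, "!=")
  ut <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  edges <- data.frame(
    from = parcellation$region_id[ut[, 1]],
    to = parcellation$region_id[ut[, 2]],
    distance_mm = d[ut], weight = a[ut],
    interhemispheric = inter[ut], stringsAsFactors = FALSE
  )
  binned <- NULL
  if (nrow(edges) > 0) {
    brk <- seq(0, max(edges$distance_mm) + 1e-9, length.out = n_bins + 1)
    bin <- cut(edges$distance_mm, brk, include.lowest = TRUE)
    binned <- do.call(rbind, lapply(split(edges, list(bin, edges$interhemispheric),
                                          drop = TRUE), function(df) {
      data.frame(bin = as.character(bin[match(df$distance_mm[1], edges$distance_mm)]),
                 interhemispheric = df$interhemispheric[1],
                 mid_mm = mean(range(df$distance_mm)),
                 mean_weight = mean(df$weight), n = nrow(df))
    }))
    rownames(binned) <- NULL
    binned <- binned[order(binned$interhemispheric, binned$mid_mm), ]
  }
  list(edges = edges, binned = binned)
}
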