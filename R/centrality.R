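# Eigenvector centrality and hub detection. The centrality solves
#   x_i = (1/lambda) * sum_j C_ij x_j
# for the leading eigenpair of the (non-negative) connectivity matrix by
# shifted power iteration: iterating (A + cI) with c = max row sum keeps
# the Perron eigenvalue strictly dominant (plain power iteration oscillates
# on bipartite spectra such as a star graph), without changing eigenvectors.

#' Eigenvector centrality
#'
#' Leading eigenvector of a non-negative connectivity matrix, sign-fixed
#' non-negative and normalized to unit sum, so values are comparable to the
#' study's 10^-3..10^-4 scale regardless of N. On disconnected graphs the
#' vector concentrates on the dominant component; components carrying no
#' mass are reported.
#'
#' @param conn `fv_conn` or non-negative matrix (weighted or binary).
#' @param tol convergence tolerance on the iterate (max abs change).
#' @param max_iter iteration cap.
#' @return list of class `fv_centrality`: `ec` (named, sums to 1),
#'   `lambda` (leading eigenvalue of the unshifted matrix), `n_iter`,
#'   `zero_mass_components` (list of region-id sets, possibly empty).
#' @export
eigenvector_centrality <- function(conn, tol = 1e-13, max_iter = 10000L) {
  a <- conn_values(conn)
  if (any(a < 0)) stop_invalid("matrix must be non-negative")
  if (sum(a) == 0) stop_invalid("matrix has no edges")
  n <- nrow(a)
  if (is.null(rownames(a)))
    dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  shift <- max(rowSums(a))
  x <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    y <- as.numeric(a %*% x) + shift * x
    y <- y / sqrt(sum(y^2))
    delta <- max(abs(y - x))
    x <- y
    if (delta < tol) break
    if (iter >= max_iter)
      stop(errorCondition(
        sprintf("power iteration did not converge in %d iterations (last delta %.3e)",
                iter, delta),
        class = c("fvconn_no_convergence", "error")))
  }
  lambda <- as.numeric(x %*% a %*% x)  # Rayleigh quotient, unshifted
  x <- pmax(x, 0)
  ec <- x / sum(x)
  names(ec) <- rownames(a)

  g <- igraph::graph_from_adjacency_matrix((a > 0) * 1, mode = "undirected")
  comp <- igraph::components(g)$membership
  mass <- tapply(ec, comp, sum)
  zero <- names(mass)[mass < 1e-10]
  zero_sets <- lapply(zero, function(cc) names(ec)[comp == as.integer(cc)])

  structure(list(ec = ec, lambda = lambda, n_iter = iter,
                 zero_mass_components = zero_sets),
            class = "fv_centrality")
}

#' Detect centrality hubs
#'
#' Z-scores the centrality values across nodes (sample sd) and returns the
#' regions with `z > z_cutoff`, optionally intersected with an absolute
#' centrality floor. The study's static free-viewing hubs use
#' EC > 14e-3 with z > 1; the dynamic per-scene states use c > 1e-4.
#'
#' @param result an `fv_centrality` (or a named numeric vector of
#'   centralities).
#' @param z_cutoff z-score threshold (default 1).
#' @param ec_cutoff absolute centrality floor, or `NULL`.
#' @return character vector of hub region ids (empty, with a warning, when
#'   the centralities have zero variance).
#' @export
detect_hubs <- function(result, z_cutoff = 1, ec_cutoff = NULL) {
  ec <- if (inherits(result, "fv_centrality")) result$ec else result
  if (is.null(names(ec))) names(ec) <- paste0("n", seq_along(ec))
  s <- sd(ec)
  if (!is.finite(s) || s == 0) {
    warning("centrality has zero variance; no hubs detected")
    return(character(0))
  }
  z <- (ec - mean(ec)) / s
  hubs <- z > z_cutoff
  if (!is.null(ec_cutoff)) hubs <- hubs & ec > ec_cutoff
  names(ec)[hubs]
}

#' Rank-centrality summary across hemispheres / subjects
#'
#' Per-region mean and sd of eigenvector centrality across a list of
#' results sharing one region order, sorted by descending mean — the
#' study's rank-centrality figure, with the structural module as grouping
#' column when a parcellation is supplied.
#'
#' @param results list of `fv_centrality` (or named numeric vectors).
#' @param parcellation optional `fv_parcellation` for the module column.
#' @return data.frame with `region_id`, `mean_ec`, `sd_ec`, `rank`, and
#'   `module` when available.
#' @export
rank_centrality_summary <- function(results, parcellation = NULL) {
  vecs <- lapply(results, function(r)
    if (inherits(r, "fv_centrality")) r$ec else r)
  ids <- names(vecs[[1]])
  for (i in seq_along(vecs)) {
    if (!identical(names(vecs[[i]]), ids)) {
      bad <- which(names(vecs[[i]]) != ids)[1]
      stop_invalid("region order mismatch in input ", i, " at position ", bad,
                   " ('", names(vecs[[i]])[bad], "' vs '", ids[bad], "')")
    }
  }
  m <- do.call(cbind, vecs)
  out <- data.frame(region_id = ids,
                    mean_ec = rowMeans(m),
                    sd_ec = apply(m, 1, sd),
                    stringsAsFactors = FALSE)
  if (length(vecs) == 1) out$sd_ec <- 0
  if (!is.null(parcellation))
    out$module <- parcellation$module[match(ids, parcellation$region_id)]
  out <- out[order(-out$mean_ec), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
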