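# Time-varying connectivity by multiplication of temporal derivatives (MTD):
#   MTD_ijt = (1/w) * sum over the window of dt_i(t) dt_j(t) / (sigma_i sigma_j)
# where dt is the first difference of the series and sigma its standard
# deviation over the whole run. Derivatives are mean-centred and sigma is
# the population (1/n) sd, which makes the full-run self-coupling exactly 1.

#' Multiplication of temporal derivatives tensor
#'
#' @param runset an `fv_bold_runset` or a plain T x N matrix.
#' @param w window length in samples for the trailing moving average
#'   (study default: 12 samples = 18 s at TR 1.5 s).
#' @param tr sampling interval (taken from the runset when available).
#' @return list of class `fv_mtd`: `values` (W x N x N array, each slice
#'   symmetric), `w`, `tr`, `window_times` (window-center timestamps, s),
#'   `zero_variance_regions`.
#' @export
mtd <- function(runset, w = 12, tr = NULL) {
  x <- if (inherits(runset, "fv_bold_runset")) runset$data else runset
  if (!is.matrix(x)) stop_invalid("runset must be an fv_bold_runset or a matrix")
  if (is.null(tr)) tr <- if (inherits(runset, "fv_bold_runset")) runset$design$tr else 1
  if (!is_count(w) || w < 2) stop_invalid("w must be an integer >= 2")
  tt <- nrow(x)
  if (tt <= w + 1) stop_invalid("need T > w + 1 timepoints")
  if (is.null(colnames(x))) colnames(x) <- paste0("n", seq_len(ncol(x)))
  n <- ncol(x)

  d <- diff(x)                              # (T-1) x N first differences
  d <- sweep(d, 2, colMeans(d))             # centre so self-coupling is exact
  sig <- sqrt(colMeans(d^2))                # population sd over the run
  flat <- sig == 0
  if (any(flat)) {
    warning("zero-variance derivative for region(s): ",
            paste(colnames(x)[flat], collapse = ", "),
            "; their couplings set to 0")
    sig[flat] <- 1
    d[, flat] <- 0
  }
  z <- sweep(d, 2, sig, "/")

  nd <- nrow(z)
  nw <- nd - w + 1L
  # cumulative sum of the outer products z_t z_t^T along time
  prods <- array(0, c(nd + 1L, n, n))
  for (t in seq_len(nd))
    prods[t + 1L, , ] <- prods[t, , ] + tcrossprod(z[t, ])
  vals <- (prods[(w + 1L):(nd + 1L), , , drop = FALSE] -
           prods[1L:nw, , , drop = FALSE]) / w
  dimnames(vals) <- list(NULL, colnames(x), colnames(x))

  # derivative sample t sits at (t - 0.5) * tr; window k spans samples
  # k..k+w-1, so its centre is (k - 1 + w/2) * tr
  window_times <- (seq_len(nw) - 1 + w / 2) * tr
  structure(list(values = vals, w = as.integer(w), tr = tr,
                 window_times = window_times,
                 zero_variance_regions = colnames(x)[flat]),
            class = "fv_mtd")
}

#' @export
print.fv_mtd <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("<fv_mtd> %d windows x %d regions, w = %d samples (%.1f s at TR %.2g)\n",
              dm[1], dm[2], x$w, x$w * x$tr, x$tr))
  invisible(x)
}

#' Epoch-averaged network states
#'
#' Averages the MTD slices whose window centre falls inside each epoch
#' (half-open `[onset, offset)`); epochs sharing a label are pooled into
#' one state per scene category.
#'
#' @param tensor an `fv_mtd`.
#' @param epochs data.frame with `label`, `onset_s`, `offset_s`.
#' @return named list of `fv_epoch_state` objects (fields `label`,
#'   `matrix`, `n_windows`).
#' @export
epoch_average <- function(tensor, epochs) {
  if (!inherits(tensor, "fv_mtd")) stop_invalid("tensor must be an fv_mtd")
  if (!nrow(epochs)) stop_invalid("epochs is empty")
  states <- list()
  for (lab in unique(epochs$label)) {
    rows <- which(epochs$label == lab)
    sel <- rep(FALSE, length(tensor$window_times))
    for (r in rows)
      sel <- sel | (tensor$window_times >= epochs$onset_s[r] &
                    tensor$window_times < epochs$offset_s[r])
    if (!any(sel))
      stop_invalid("epoch '", lab, "' covers no MTD window centre")
    sl <- tensor$values[sel, , , drop = FALSE]
    m <- apply(sl, c(2, 3), mean)
    states[[lab]] <- structure(list(label = lab, matrix = m,
                                    n_windows = sum(sel)),
                               class = "fv_epoch_state")
  }
  states
}

#' Windowed eigenvector-centrality traces
#'
#' Per window: absolute MTD slice, zero diagonal, eigenvector centrality.
#' Windows where the iteration fails (or the slice is empty) yield a
#' missing column and a warning.
#'
#' @param tensor an `fv_mtd`.
#' @return N x W matrix of centralities (rows = regions), attribute
#'   `window_times`.
#' @export
windowed_centrality <- function(tensor) {
  if (!inherits(tensor, "fv_mtd")) stop_invalid("tensor must be an fv_mtd")
  dm <- dim(tensor$values)
  out <- matrix(NA_real_, dm[2], dm[1],
                dimnames = list(dimnames(tensor$values)[[2]], NULL))
  failed <- integer(0)
  for (k in seq_len(dm[1])) {
    sl <- abs(tensor$values[k, , ])
    diag(sl) <- 0
    res <- tryCatch(eigenvector_centrality(sl), error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, k) else out[, k] <- res$ec
  }
  if (length(failed))
    warning("centrality unavailable for window(s): ",
            paste(failed, collapse = ", "))
  attr(out, "window_times") <- tensor$window_times
  out
}

#' Compare hub membership across network states
#'
#' Runs hub detection on every epoch-averaged state (|MTD|, zero diagonal),
#' tabulates pairwise Jaccard overlap of the hub sets, and flags regions
#' that are hubs in two or more states as poly-functional.
#'
#' @param states list of `fv_epoch_state` (from [epoch_average()]).
#' @param z_cutoff z-score threshold (default 1).
#' @param ec_cutoff absolute centrality floor (study's dynamic states:
#'   1e-4).
#' @return list with `hubs` (named list per state), `jaccard` (matrix),
#'   `poly_functional` (character vector), `centrality` (named list of
#'   `fv_centrality`).
#' @export
state_hub_comparison <- function(states, z_cutoff = 1, ec_cutoff = 1e-4) {
  if (length(states) < 2) stop_invalid("need at least 2 states")
  cent <- lapply(states, function(s) {
    m <- abs(s$matrix)
    diag(m) <- 0
    eigenvector_centrality(m)
  })
  hubs <- lapply(cent, detect_hubs, z_cutoff = z_cutoff, ec_cutoff = ec_cutoff)
  labs <- names(states)
  jac <- matrix(1, length(states), length(states), dimnames = list(labs, labs))
  for (i in seq_along(states)) for (j in seq_along(states)) if (i != j) {
    u <- union(hubs[[i]], hubs[[j]])
    jac[i, j] <- if (length(u)) length(intersect(hubs[[i]], hubs[[j]])) / length(u) else 1
  }
  counts <- table(unlist(hubs))
  poly <- names(counts)[counts >= 2]
  list(hubs = hubs, jaccard = jac, poly_functional = poly, centrality = cent)
}
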