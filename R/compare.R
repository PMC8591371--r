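# Structure-function comparison: matrix-to-matrix Spearman similarity and
# node-level structure-function correlation with an OLS fit and 95%
# prediction interval.

#' Pairwise Spearman similarity between connectivity matrices
#'
#' Vectorizes the upper triangle of every matrix (diagonal excluded,
#' thresholded-out zero edges kept — absences are informative) and computes
#' Spearman's rho for every pair. Pairs are annotated as
#' intersubject-structural, intersubject-functional, or
#' intrasubject-cross-modal from the matrix kinds and labels.
#'
#' @param mats list of `fv_conn` (or matrices) sharing N and region order.
#' @param labels identifiers (e.g. subject ids); defaults to list names.
#' @param kinds `"functional"`/`"structural"` per matrix; taken from the
#'   `fv_conn` objects when omitted.
#' @return list of class `fv_similarity`: `rho` (matrix), `pairs`
#'   (data.frame with a `block` column).
#' @export
matrix_similarity <- function(mats, labels = names(mats), kinds = NULL) {
  if (length(mats) < 2) stop_invalid("need at least 2 matrices")
  vals <- lapply(mats, conn_values)
  n <- nrow(vals[[1]])
  ord <- rownames(vals[[1]])
  for (i in seq_along(vals)) {
    if (nrow(vals[[i]]) != n)
      stop_invalid("matrix ", i, " has different size")
    if (!is.null(ord) && !identical(rownames(vals[[i]]), ord))
      stop_invalid("matrix ", i, " has a different region order")
  }
  if (is.null(kinds))
    kinds <- vapply(mats, function(m)
      if (inherits(m, "fv_conn")) m$kind else "unknown", character(1))
  if (is.null(labels)) labels <- paste0("m", seq_along(mats))

  v <- vapply(vals, upper_vec, numeric(n * (n - 1) / 2))
  rho <- cor(v, method = "spearman")
  dimnames(rho) <- list(paste(labels, kinds, sep = ":"),
                        paste(labels, kinds, sep = ":"))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  block <- function(i, j) {
    if (kinds[i] != kinds[j]) {
      if (labels[i] == labels[j]) "intrasubject-cross-modal" else "cross-modal"
    } else paste0("intersubject-", kinds[i])
  }
  pairs <- data.frame(
    a = rownames(rho)[idx[, 1]], b = rownames(rho)[idx[, 2]],
    rho = rho[idx],
    block = mapply(block, idx[, 1], idx[, 2]),
    stringsAsFactors = FALSE
  )
  structure(list(rho = rho, pairs = pairs), class = "fv_similarity")
}

#' Node-level structure-function correlation and fit
#'
#' Spearman's rho between corresponding edges of an average structural and
#' an average functional network: pooled over all unique pairs, and
#' per-node over each node's row. An OLS fit of functional on structural
#' weights provides the regression line with 95% prediction intervals, as
#' in the study's structure-function scatter.
#'
#' @param struct_avg,func_avg `fv_conn` or matrices on one parcellation.
#' @param drop_zero_struct drop edges with zero structural weight before
#'   correlating.
#' @return list with `pooled_rho`, `per_node` (named vector), `fit` (the
#'   `lm`), `prediction` (data.frame x, fit, lwr, upr).
#' @export
node_structure_function <- function(struct_avg, func_avg,
                                    drop_zero_struct = FALSE) {
  s <- conn_values(struct_avg)
  f <- conn_values(func_avg)
  if (!identical(dim(s), dim(f)))
    stop_invalid("matrices must share dimensions")
  sv <- upper_vec(s)
  fv <- upper_vec(f)
  if (drop_zero_struct) {
    keep <- sv != 0
    sv <- sv[keep]
    fv <- fv[keep]
  }
  if (all(sv == 0) || all(fv == 0)) {
    warning("a matrix is all zero; correlation undefined")
    return(list(pooled_rho = NA_real_, per_node = NULL, fit = NULL,
                prediction = NULL))
  }
  pooled <- suppressWarnings(cor(sv, fv, method = "spearman"))

  n <- nrow(s)
  per_node <- vapply(seq_len(n), function(i) {
    a <- s[i, -i]
    b <- f[i, -i]
    if (sd(a) == 0 || sd(b) == 0) NA_real_
    else suppressWarnings(cor(a, b, method = "spearman"))
  }, numeric(1))
  names(per_node) <- rownames(s)

  df <- data.frame(x = sv, y = fv)
  fit <- lm(y ~ x, data = df)
  grid <- data.frame(x = seq(min(sv), max(sv), length.out = 100))
  pr <- predict(fit, newdata = grid, interval = "prediction", level = 0.95)
  prediction <- cbind(grid, as.data.frame(pr))

  list(pooled_rho = pooled, per_node = per_node, fit = fit,
       prediction = prediction)
}
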