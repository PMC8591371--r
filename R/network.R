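#' Connectivity matrix container
#'
#' Symmetric N x N matrix with zero diagonal, region ids as dimnames, and
#' provenance: kind (functional/structural), weighted or binary, and the
#' threshold applied (if any).
#'
#' @param values numeric N x N matrix, symmetric to 1e-12, zero diagonal.
#' @param kind `"functional"` or `"structural"`.
#' @param weighted logical; binary matrices must be 0/1.
#' @param threshold_record list describing the thresholding step, or `NULL`.
#' @param pvalues optional symmetric matrix of edge p-values.
#' @return object of class `fv_conn`.
#' @export
conn_matrix <- function(values, kind = c("functional", "structural"),
                        weighted = TRUE, threshold_record = NULL,
                        pvalues = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_invalid("values must be a square matrix")
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("n", seq_len(nrow(values))),
                             paste0("n", seq_len(nrow(values))))
  if (max(abs(values - t(values))) > 1e-12)
    stop_invalid("values must be symmetric (tolerance 1e-12)")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (!weighted && !all(values %in% c(0, 1)))
    stop_invalid("binary matrix must contain only 0/1")
  structure(list(values = values, kind = kind, weighted = weighted,
                 threshold_record = threshold_record, pvalues = pvalues,
                 regions = rownames(values)),
            class = "fv_conn")
}

#' @export
print.fv_conn <- function(x, ...) {
  n <- nrow(x$values)
  e <- sum(x$values[upper.tri(x$values)] != 0)
  cat(sprintf("<fv_conn> %s, %s, %d regions, %d edges (density %.3f)\n",
              x$kind, if (x$weighted) "weighted" else "binary", n, e,
              e / (n * (n - 1) / 2)))
  if (!is.null(x$threshold_record))
    cat("  threshold:", paste(names(x$threshold_record),
                              unlist(x$threshold_record),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Accept an fv_conn or a plain matrix.
conn_values <- function(x) {
  if (inherits(x, "fv_conn")) x$values
  else if (is.matrix(x)) x
  else stop_invalid("expected an fv_conn or a matrix")
}

#' Free-viewing correlation network from a BOLD run
#'
#' Optionally band-limits every regional series by MODWT level selection,
#' then computes all pairwise Pearson correlations; the stored weights are
#' absolute correlations (the study's convention), with two-sided p-values
#' from the t distribution kept for FDR thresholding. Zero-variance regions
#' get all their edges set to 0 (p = 1) with a warning.
#'
#' @param runset an `fv_bold_runset`, or a plain T x N matrix.
#' @param wavelet an [wavelet_spec()] or `NULL` to skip filtering.
#' @param tr sampling interval (taken from the runset when available).
#' @return weighted functional `fv_conn` carrying `pvalues`.
#' @export
correlation_matrix <- function(runset, wavelet = NULL, tr = NULL) {
  x <- if (inherits(runset, "fv_bold_runset")) runset$data else runset
  if (!is.matrix(x)) stop_invalid("runset must be an fv_bold_runset or a matrix")
  if (nrow(x) < 10) stop_invalid("need at least 10 timepoints")
  if (ncol(x) < 2) stop_invalid("need at least 2 regions")
  if (is.null(tr) && inherits(runset, "fv_bold_runset")) tr <- runset$design$tr
  if (is.null(colnames(x))) colnames(x) <- paste0("n", seq_len(ncol(x)))

  if (!is.null(wavelet))
    x <- apply(x, 2, modwt_bandlimit, spec = wavelet, tr = tr)

  sds <- apply(x, 2, pop_sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("zero-variance region(s): ",
            paste(colnames(x)[flat], collapse = ", "),
            "; their edges set to 0")
    x[, flat] <- matrix(rnorm(nrow(x) * sum(flat)), nrow(x))  # placeholder
  }
  r <- cor(x)
  tt <- nrow(x)
  tstat <- r * sqrt((tt - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = tt - 2)
  if (any(flat)) {
    r[flat, ] <- 0; r[, flat] <- 0
    p[flat, ] <- 1; p[, flat] <- 1
  }
  diag(r) <- 0
  diag(p) <- 1
  conn_matrix(abs(r), kind = "functional", weighted = TRUE, pvalues = p)
}

#' FDR-threshold a correlation network
#'
#' Benjamini-Hochberg step-up over the N(N-1)/2 unique region pairs; edges
#' whose adjusted p-value is not below `q` are set to 0. The study uses
#' q = 0.01.
#'
#' @param conn weighted functional `fv_conn` with p-values.
#' @param q false discovery rate.
#' @return list with `weighted` (sparsified weights) and `binary`
#'   (survivor indicator), both `fv_conn` with a `threshold_record`.
#' @export
fdr_threshold <- function(conn, q = 0.01) {
  if (!inherits(conn, "fv_conn") || is.null(conn$pvalues))
    stop_state("fdr_threshold needs an fv_conn carrying p-values")
  if (q <= 0 || q >= 1) stop_invalid("q must be in (0, 1)")
  p <- conn$pvalues
  ut <- upper.tri(p)
  padj <- p.adjust(p[ut], method = "BH")
  keep <- matrix(FALSE, nrow(p), ncol(p))
  keep[ut] <- padj < q
  keep <- keep | t(keep)
  rec <- list(method = "BH", q = q)
  w <- conn$values
  w[!keep] <- 0
  b <- matrix(as.numeric(keep), nrow(p), dimnames = dimnames(conn$values))
  list(
    weighted = conn_matrix(w, kind = conn$kind, weighted = TRUE,
                           threshold_record = rec, pvalues = conn$pvalues),
    binary = conn_matrix(b, kind = conn$kind, weighted = FALSE,
                         threshold_record = rec)
  )
}

#' Structural network from a streamline-count matrix
#'
#' Keeps pairs with strictly more than `min_streamlines` streamlines (the
#' study: n > 10) and log-scales the surviving counts; also returns the
#' binarized survivor network used for the graph measures.
#'
#' @param counts symmetric non-negative integer matrix.
#' @param min_streamlines strict lower cutoff.
#' @param log_base base of the logarithmic scaling.
#' @return list with `weighted` (log counts) and `binary` `fv_conn`.
#' @export
structural_matrix <- function(counts, min_streamlines = 10, log_base = 10) {
  counts <- conn_values(counts)
  if (any(counts < 0)) stop_invalid("streamline counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-12) stop_invalid("counts must be symmetric")
  if (log_base <= 1) stop_invalid("log_base must be > 1")
  keep <- counts > min_streamlines
  diag(keep) <- FALSE
  w <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  w[keep] <- log(counts[keep]) / log(log_base)
  rec <- list(method = "count", min_streamlines = min_streamlines,
              log_base = log_base)
  list(
    weighted = conn_matrix(w, kind = "structural", weighted = TRUE,
                           threshold_record = rec),
    binary = conn_matrix(matrix(as.numeric(keep), nrow(counts),
                                dimnames = dimnames(counts)),
                         kind = "structural", weighted = FALSE,
                         threshold_record = rec)
  )
}
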