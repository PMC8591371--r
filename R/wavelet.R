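# Maximal overlap discrete wavelet transform (MODWT), circular boundary.
# Pyramid algorithm with filters rescaled by 1/sqrt(2) per stage; the
# multiresolution analysis (MRA) details and smooth add back to the input
# exactly, which is the identity the band-limiting step relies on.

# Daubechies extremal-phase scaling filters (unit-energy, orthonormal DWT
# convention). "dN" has N taps (N/2 vanishing moments).
daubechies_filters <- function(family) {
  s3 <- sqrt(3)
  g <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)),
    d8 = c(0.32580342805130, 1.01094571509183, 0.89220013824676,
           -0.03957502623564, -0.26450716736904, 0.04361630047418,
           0.04650360107098, -0.01498698933036) / sqrt(2),
    stop_invalid("unknown wavelet family '", family,
                 "' (available: haar, d4, d8)")
  )
  h <- rev(g) * (-1)^(seq_along(g) - 1)  # quadrature mirror filter
  list(g = g, h = h)
}

#' Wavelet specification for band-limited reconstruction
#'
#' @param family Daubechies family: `"haar"`, `"d4"` (default; 4-tap
#'   extremal phase), `"d8"`.
#' @param n_levels decomposition depth (study: 5 levels at TR 1.5 s).
#' @param keep_levels detail levels retained in the reconstruction; the
#'   study concentrates on levels 2 and 3, the low-frequency band where
#'   movie-driven hemodynamic events live.
#' @param keep_smooth also add the level-`n_levels` smooth (scaling) part.
#' @param boundary only `"circular"` is implemented.
#' @return list of class `fv_wavelet_spec`.
#' @export
wavelet_spec <- function(family = "d4", n_levels = 5, keep_levels = c(2, 3),
                         keep_smooth = FALSE, boundary = "circular") {
  if (!is_count(n_levels) || n_levels < 1) stop_invalid("n_levels must be >= 1")
  if (length(keep_levels) && (any(keep_levels < 1) || any(keep_levels > n_levels)))
    stop_invalid("keep_levels must lie in 1..n_levels")
  if (!identical(boundary, "circular"))
    stop_invalid("only circular boundary handling is implemented")
  daubechies_filters(family)  # validate family early
  structure(list(family = family, n_levels = as.integer(n_levels),
                 keep_levels = as.integer(sort(unique(keep_levels))),
                 keep_smooth = isTRUE(keep_smooth), boundary = boundary),
            class = "fv_wavelet_spec")
}

# One circular MODWT filtering stage: y[t] = sum_l f[l] x[(t - step*l) mod n]
modwt_filt <- function(x, f, step) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    shift <- (step * (l - 1)) %% n
    y <- y + f[l] * x[((idx - 1 - shift) %% n) + 1]
  }
  y
}

# Adjoint stage used by the inverse: y[t] = sum_l f[l] x[(t + step*l) mod n]
modwt_filt_adj <- function(x, f, step) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    shift <- (step * (l - 1)) %% n
    y <- y + f[l] * x[((idx - 1 + shift) %% n) + 1]
  }
  y
}

#' MODWT decomposition
#'
#' @param x numeric series.
#' @param spec an [wavelet_spec()].
#' @return list with `W` (list of detail coefficient vectors, level 1 =
#'   highest frequency), `V` (final smooth coefficients), `spec`.
#' @export
modwt <- function(x, spec = wavelet_spec()) {
  filt <- daubechies_filters(spec$family)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  if (length(x) < length(gt) * 2^(spec$n_levels - 1))
    stop_invalid("series shorter than the level-", spec$n_levels,
                 " filter support (", length(gt) * 2^(spec$n_levels - 1),
                 " samples needed)")
  v <- x
  W <- vector("list", spec$n_levels)
  for (j in seq_len(spec$n_levels)) {
    step <- 2^(j - 1)
    W[[j]] <- modwt_filt(v, ht, step)
    v <- modwt_filt(v, gt, step)
  }
  list(W = W, V = v, spec = spec)
}

#' MODWT multiresolution analysis
#'
#' Splits `x` into additive detail components `D1..Dn` plus the smooth `S`,
#' with `x = D1 + ... + Dn + S` exactly (circular boundary). Detail level j
#' nominally covers the octave `(fs/2^(j+1), fs/2^j]`.
#'
#' @inheritParams modwt
#' @param tr sampling interval, s; used only to annotate band edges.
#' @return list with `D` (list of detail series), `S` (smooth series) and
#'   `bands` (data.frame of nominal band edges in Hz, when `tr` given).
#' @export
modwt_mra <- function(x, spec = wavelet_spec(), tr = NULL) {
  dec <- modwt(x, spec)
  filt <- daubechies_filters(spec$family)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  J <- spec$n_levels

  invert_from <- function(Wj, Vj, j_top) {
    # bring (W at level j_top, V at level j_top) down to level 0
    v <- Vj
    w <- Wj
    for (j in rev(seq_len(j_top))) {
      step <- 2^(j - 1)
      v <- modwt_filt_adj(w, ht, step) + modwt_filt_adj(v, gt, step)
      w <- numeric(length(v))  # levels below j_top carry no coefficients
    }
    v
  }
  zeros <- numeric(length(x))
  D <- lapply(seq_len(J), function(j) invert_from(dec$W[[j]], zeros, j))
  S <- invert_from(zeros, dec$V, J)

  bands <- NULL
  if (!is.null(tr)) {
    fs <- 1 / tr
    bands <- data.frame(level = seq_len(J),
                        f_low_hz = fs / 2^(seq_len(J) + 1),
                        f_high_hz = fs / 2^seq_len(J))
  }
  list(D = D, S = S, bands = bands, spec = spec)
}

#' Band-limit a series by MODWT level selection
#'
#' Reconstructs the series from the detail levels in `spec$keep_levels`
#' (plus the smooth when `spec$keep_smooth`). Keeping all levels and the
#' smooth reproduces the input exactly.
#'
#' @inheritParams modwt_mra
#' @return filtered series, same length as `x`.
#' @export
modwt_bandlimit <- function(x, spec = wavelet_spec(), tr = NULL) {
  mra <- modwt_mra(x, spec, tr = tr)
  out <- numeric(length(x))
  for (j in spec$keep_levels) out <- out + mra$D[[j]]
  if (spec$keep_smooth) out <- out + mra$S
  attr(out, "bands") <- mra$bands
  out
}
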