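#' Gamma-variate hemodynamic response function
#'
#' `h(t) = (t/tau)^a * exp(-(t - a*tau)/tau)`, peak-normalized so that
#' `h(a*tau) = 1`. Defaults `a = 8.6`, `tau = 0.547` s give a response
#' peaking near 4.7 s, the common primate/human default.
#'
#' @param t time, s (vectorized; `h(t) = 0` for `t < 0`).
#' @param a shape parameter (dimensionless).
#' @param tau time constant, s.
#' @return HRF values, unit peak.
#' @export
gamma_hrf <- function(t, a = 8.6, tau = 0.547) {
  if (a <= 0 || tau <= 0) stop_invalid("a and tau must be positive")
  out <- numeric(length(t))
  pos <- t > 0
  # log-space: log h = a*log(t/tau) - (t - a*tau)/tau, peak log = a*log(a)
  out[pos] <- exp(a * log(t[pos] / tau) - (t[pos] - a * tau) / tau - a * log(a))
  out
}

#' Build the block-design stimulus regressor
#'
#' ON/OFF boxcar (1 during movie blocks starting at t = 0, 0 during
#' darkness) convolved with a unit-peak HRF sampled at the TR, truncated to
#' the run length. With a 30 s ON / 30 s OFF design at TR 1.5 s the raw
#' boxcar is 20 ones followed by 20 zeros per cycle.
#'
#' @param design an `fv_run_design`.
#' @param hrf_kernel HRF samples at the TR grid (first sample = t 0). The
#'   default evaluates [gamma_hrf()] over 32 s. Pass `1` for an identity
#'   (delta) HRF.
#' @return list with `regressor` (convolved, length T), `boxcar` (raw 0/1,
#'   length T) and `hrf_kernel`.
#' @export
build_block_regressor <- function(design,
                                  hrf_kernel = gamma_hrf(seq(0, 32, by = design$tr))) {
  if (design$block_on + design$block_off > design$duration)
    stop_invalid("one ON+OFF cycle exceeds the run duration")
  tt <- design$n_volumes
  times <- (seq_len(tt) - 1) * design$tr
  boxcar <- as.numeric(times %% (design$block_on + design$block_off) < design$block_on)
  full <- convolve(boxcar, rev(hrf_kernel), type = "open")[seq_len(tt)]
  if (all(hrf_kernel >= 0)) full <- pmax(full, 0)  # zap FFT round-off
  list(regressor = full, boxcar = boxcar, hrf_kernel = hrf_kernel)
}

#' Temporal signal-to-noise ratio
#'
#' Mean of the series divided by its population (1/n) standard deviation.
#' A zero-variance series returns `Inf` with attribute
#' `zero_variance = TRUE`.
#'
#' @param series numeric vector, length >= 2.
#' @return scalar tSNR.
#' @export
tsnr <- function(series) {
  if (!is.numeric(series) || length(series) < 2)
    stop_invalid("series must be numeric with length >= 2")
  s <- pop_sd(series)
  if (s == 0) return(structure(Inf, zero_variance = TRUE))
  mean(series) / s
}

#' Coherence specification
#'
#' @param f0 fundamental stimulation frequency, Hz (one movie/darkness cycle;
#'   1/60 s for the study's 30 s ON / 30 s OFF design).
#' @param delta_f full band width around `f0`, Hz; `NULL` means +/- 2 DFT
#'   bins around the `f0` bin.
#' @param threshold coherence level regarded as stimulus-locked (study: 0.35).
#' @return list of class `fv_coherence_spec`.
#' @export
coherence_spec <- function(f0 = 1 / 60, delta_f = NULL, threshold = 0.35) {
  if (f0 <= 0) stop_invalid("f0 must be positive")
  if (threshold < 0 || threshold > 1) stop_invalid("threshold must be in [0, 1]")
  structure(list(f0 = f0, delta_f = delta_f, threshold = threshold),
            class = "fv_coherence_spec")
}

#' Coherence of a series at the stimulation frequency
#'
#' `C(f0) = A(f0) / sqrt(sum over band of A(f)^2)` where `A(f)` is the
#' amplitude spectrum of the demeaned series. The numerator is the amplitude
#' at the DFT bin nearest `f0` (a warning is issued if `f0` is off-grid);
#' the denominator sums bins within `[f0 - delta_f/2, f0 + delta_f/2]`.
#' Result in `[0, 1]`; if the band carries no power the coherence is 0.
#'
#' @param series numeric vector (one region's or voxel's time series).
#' @param spec an `fv_coherence_spec`.
#' @param tr sampling interval, s.
#' @param detrend remove a linear trend instead of just the mean.
#' @return coherence in `[0, 1]`, with attribute `f0_bin_hz` (the frequency
#'   actually used).
#' @export
coherence_at_f0 <- function(series, spec = coherence_spec(), tr = 1.5,
                            detrend = FALSE) {
  tt <- length(series)
  if (tt < 8) stop_invalid("series too short for a spectral estimate")
  if (spec$f0 >= 1 / (2 * tr)) stop_invalid("f0 must be below the Nyquist frequency")
  x <- if (detrend) stats::residuals(lm(series ~ seq_len(tt)))
       else series - mean(series)
  amp <- Mod(fft(x))[2:(floor(tt / 2) + 1)]
  freqs <- seq_along(amp) / (tt * tr)

  i0 <- which.min(abs(freqs - spec$f0))
  if (abs(freqs[i0] - spec$f0) > 1e-9 * max(1, spec$f0))
    warning("f0 is off the DFT grid; snapped to nearest bin at ",
            signif(freqs[i0], 6), " Hz")
  if (is.null(spec$delta_f)) {
    band <- seq(max(1L, i0 - 2L), min(length(amp), i0 + 2L))
  } else {
    band <- which(freqs >= spec$f0 - spec$delta_f / 2 &
                  freqs <= spec$f0 + spec$delta_f / 2)
  }
  if (!length(band)) stop_invalid("frequency band around f0 is empty")
  den <- sqrt(sum(amp[band]^2))
  if (den <= max(amp) * 1e-9) {  # no power anywhere near the band
    warning("no spectral power in the analysis band; coherence set to 0")
    return(structure(0, f0_bin_hz = freqs[i0]))
  }
  structure(min(1, amp[i0] / den), f0_bin_hz = freqs[i0])
}
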