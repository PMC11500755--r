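#' Design a Gaussian complex-demodulation kernel
#'
#' Builds the Gaussian low-pass FIR used by [complex_demodulate()]. With a
#' Gaussian low-pass, complex demodulation is equivalent to a Gabor transform,
#' so the kernel is fully characterized by the full width at half maximum
#' (FWHM) of its *power* envelope in time; the spectral power FWHM follows
#' from the Gabor time-bandwidth product `2*log(2)/pi` (about 0.4413 when time
#' is in seconds and frequency in Hz). The default 31.6 ms temporal FWHM gives
#' a spectral power FWHM of about 14 Hz.
#'
#' @param temporal_fwhm FWHM of the power envelope in ms (default 31.6).
#' @param rate sampling rate in Hz.
#' @param truncate tap support, in standard deviations of the amplitude
#'   Gaussian (default 4; < 1e-3 tail mass).
#' @return An object of class `demod_kernel`: the taps (unit DC gain), the
#'   sampling rate, and the *measured* temporal and spectral power FWHMs.
#' @examples
#' k <- design_demod_kernel(31.6, 1000)
#' k$temporal_fwhm_ms * k$spectral_fwhm_hz / 1000  # ~ 2*log(2)/pi
#' @export
design_demod_kernel <- function(temporal_fwhm = 31.6, rate = 1000,
                                truncate = 4) {
  if (!is.numeric(temporal_fwhm) || length(temporal_fwhm) != 1L ||
      !is.finite(temporal_fwhm) || temporal_fwhm <= 0)
    stop("temporal_fwhm must be a positive number (ms)")
  if (temporal_fwhm * rate / 1000 < 2)
    stop("temporal_fwhm shorter than 2 samples at this rate")
  # power envelope exp(-t^2/sigma^2) has FWHM 2*sigma*sqrt(log(2))
  sigma_ms <- temporal_fwhm / (2 * sqrt(log(2)))
  sigma_samp <- sigma_ms * rate / 1000
  half <- ceiling(truncate * sigma_samp)
  j <- seq(-half, half)
  taps <- exp(-j^2 / (2 * sigma_samp^2))
  taps <- taps / sum(taps)

  # measure the power FWHMs rather than quoting the design formula
  t_ms <- j * 1000 / rate
  pw <- taps^2
  temporal_meas <- fwhm_of(t_ms, pw)
  f <- seq(0, rate / 2, by = 0.05)
  H <- vapply(f, function(ff) abs(sum(taps * exp(-2i * pi * ff * j / rate))),
              numeric(1))
  # one-sided profile peaks at f = 0: full width = 2 * half-power frequency
  spectral_half <- fwhm_of(f, H^2)
  structure(list(taps = taps, rate = rate, sigma_ms = sigma_ms,
                 half_support = half,
                 temporal_fwhm_ms = temporal_meas,
                 spectral_fwhm_hz = 2 * spectral_half),
            class = "demod_kernel")
}

# FWHM of a sampled unimodal profile by linear interpolation at half maximum.
fwhm_of <- function(x, y) {
  ymax <- max(y)
  above <- y >= ymax / 2
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 > 1)
    approx(y[c(i1 - 1, i1)], x[c(i1 - 1, i1)], xout = ymax / 2)$y else x[i1]
  right <- if (i2 < length(x))
    approx(y[c(i2, i2 + 1)], x[c(i2, i2 + 1)], xout = ymax / 2)$y else x[i2]
  right - left
}

#' @export
print.demod_kernel <- function(x, ...) {
  cat(sprintf(
    "Gaussian demodulation kernel: %d taps @ %g Hz\n  temporal power FWHM %.2f ms, spectral power FWHM %.2f Hz\n",
    length(x$taps), x$rate, x$temporal_fwhm_ms, x$spectral_fwhm_hz))
  invisible(x)
}

#' Complex demodulation on a regular time-frequency grid
#'
#' Shifts each requested carrier frequency to baseband by multiplication with
#' a complex exponential, applies the Gaussian low-pass, and samples the
#' result every `time_step` ms. The amplitude is scaled so that a unit
#' sinusoid at a grid frequency reads amplitude 1 (factor 2 restores the
#' negative-frequency half). Output bins whose kernel support overruns the
#' signal are returned as `NA` rather than zero-padded.
#'
#' @param x numeric vector, one channel of voltage samples.
#' @param rate sampling rate in Hz.
#' @param freqs carrier frequencies in Hz (all below Nyquist).
#' @param kernel a [design_demod_kernel()] object (default: 31.6 ms at `rate`).
#' @param time_step output step in ms (default 10).
#' @param t0 time of the first sample in ms (default 0).
#' @return A `timefreq_map`: `amplitude` (time x frequency matrix, microvolts,
#'   proportional to the square root of power), `times_ms`, `freqs`.
#' @export
complex_demodulate <- function(x, rate, freqs, kernel = NULL, time_step = 10,
                               t0 = 0) {
  if (any(freqs >= rate / 2))
    stop("carrier frequency at or above Nyquist (", rate / 2, " Hz)")
  if (any(freqs < 0)) stop("carrier frequencies must be non-negative")
  kernel <- kernel %||% design_demod_kernel(rate = rate)
  stopifnot(inherits(kernel, "demod_kernel"), kernel$rate == rate)
  n <- length(x)
  step_samp <- time_step * rate / 1000
  centers <- seq(1, n, by = step_samp)
  half <- kernel$half_support
  valid <- centers - half >= 1 & centers + half <= n
  amp <- matrix(NA_real_, length(centers), length(freqs))
  if (any(valid)) {
    amp[valid, ] <- cpp_demod_amplitude(x, as.integer(round(centers[valid])),
                                        kernel$taps, freqs, rate)
  }
  structure(list(amplitude = amp,
                 times_ms = t0 + (centers - 1) * 1000 / rate,
                 freqs = freqs, rate = rate),
            class = "timefreq_map")
}

# Fast path used by the pipeline: amplitude at explicit 1-based sample
# indices. All slices must fit inside x.
demod_amplitude_at <- function(x, centers, kernel, freqs) {
  half <- kernel$half_support
  if (any(centers - half < 1) || any(centers + half > length(x)))
    stop("demodulation kernel overruns the signal for some requested bins")
  cpp_demod_amplitude(x, as.integer(centers), kernel$taps, freqs, kernel$rate)
}

#' High-gamma band amplitude from a time-frequency map
#'
#' Averages the amplitude over the 5-Hz frequency bins whose centers fall in
#' `band` (inclusive); the default 70-110 Hz band covers exactly nine bins on
#' the standard grid.
#'
#' @param map a `timefreq_map` from [complex_demodulate()], or a plain
#'   time x frequency amplitude matrix with a `freqs` attribute/argument.
#' @param band numeric length 2, Hz.
#' @param freqs frequency axis, required when `map` is a bare matrix.
#' @return numeric vector of band amplitude per time bin.
#' @export
band_amplitude <- function(map, band = c(70, 110), freqs = NULL) {
  if (inherits(map, "timefreq_map")) {
    freqs <- map$freqs
    amp <- map$amplitude
  } else {
    amp <- map
    if (is.null(freqs)) stop("freqs required for a bare amplitude matrix")
  }
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel) || band[1] < min(freqs) || band[2] > max(freqs))
    stop("band [", band[1], ", ", band[2], "] Hz not covered by the frequency axis")
  rowMeans(amp[, sel, drop = FALSE])
}

#' Percent change relative to the baseline mean
#'
#' `100 * (a - b) / b`, the normalized high-gamma measure. `baseline` is
#' recycled along rows when `x` is a matrix with one baseline per row (e.g.
#' trials x bins against one baseline mean per trial).
#'
#' @param x amplitude (vector or trials x bins matrix).
#' @param baseline baseline mean amplitude (scalar or one per row of `x`);
#'   must be strictly positive.
#' @return percent-change values, same shape as `x`.
#' @export
percent_change <- function(x, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline means must be finite and strictly positive")
  if (is.matrix(x)) {
    if (length(baseline) == 1L) baseline <- rep(baseline, nrow(x))
    if (length(baseline) != nrow(x))
      stop("need one baseline per row of x")
    100 * (x - baseline) / baseline
  } else {
    100 * (x - baseline) / baseline
  }
}
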