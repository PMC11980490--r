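#' Amplitude statistics of a plant electrical signal
#'
#' @param s A [phyto_signal()].
#' @return A list of class `signal_stats` with `max_v`, `min_v`, `peak_v`
#'   (peak-to-peak, `max_v - min_v`) in volts and `period_ms` (from
#'   [estimate_period()]; `NA` when the signal has no periodic structure).
#' @export
#' @examples
#' s <- phyto_signal(sin(2 * pi * 50 * (0:3999) / 2000), fs = 2000)
#' signal_stats(s)
signal_stats <- function(s) {
  stopifnot(inherits(s, "phyto_signal"))
  mx <- max(s$samples); mn <- min(s$samples)
  structure(list(max_v = mx, min_v = mn, peak_v = mx - mn,
                 period_ms = estimate_period(s)),
            class = "signal_stats")
}

#' @export
print.signal_stats <- function(x, ...) {
  cat(sprintf("<signal_stats> max %.4g V, min %.4g V, peak-to-peak %.4g V, period %s\n",
              x$max_v, x$min_v, x$peak_v,
              if (is.na(x$period_ms)) "undefined" else sprintf("%.3f ms", x$period_ms)))
  invisible(x)
}

# Biased normalised autocorrelation up to lag.max, via FFT (linear, i.e.
# zero-padded, so lags do not wrap).
acf_biased <- function(x, lag.max) {
  n <- length(x)
  x <- x - mean(x)
  v <- sum(x^2) / n
  if (v <= 0) return(NULL)
  nf <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, nf - n)))
  r <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / nf / n
  r[seq_len(lag.max + 1L)] / v
}

#' Oscillation period by autocorrelation
#'
#' The period is the lag of the first local maximum of the biased normalised
#' autocorrelation beyond lag 0 whose value exceeds `threshold`, refined by
#' quadratic interpolation over the neighbouring lags. Autocorrelation (rather
#' than zero-crossing counting) is robust to the slow sub-5 Hz component
#' superposed on the fast carrier oscillation.
#'
#' @param s A [phyto_signal()].
#' @param threshold Minimum autocorrelation value for a qualifying peak.
#' @param max_lag_s Longest lag searched, seconds.
#' @return Period in milliseconds, or `NA_real_` for aperiodic input
#'   (constant signals, white noise).
#' @export
#' @examples
#' estimate_period(phyto_signal(sin(2 * pi * 40 * (0:1999) / 2000), 2000))  # 25 ms
estimate_period <- function(s, threshold = 0.2, max_lag_s = 1) {
  stopifnot(inherits(s, "phyto_signal"))
  n <- length(s$samples)
  lag.max <- min(n - 2L, max(4L, floor(max_lag_s * s$fs)))
  r <- acf_biased(s$samples, lag.max)
  if (is.null(r)) return(NA_real_)  # constant signal
  # local maxima over lags 1..lag.max-1 (index k+1 in r)
  for (k in seq(2L, lag.max)) {
    if (r[k] > r[k - 1L] && r[k] >= r[k + 1L] && r[k] > threshold) {
      denom <- r[k - 1L] - 2 * r[k] + r[k + 1L]
      delta <- if (denom < 0) 0.5 * (r[k - 1L] - r[k + 1L]) / denom else 0
      return(1000 * ((k - 1L) + delta) / s$fs)
    }
  }
  NA_real_
}

#' One-sided Fourier amplitude spectrum
#'
#' Sinusoid-amplitude normalisation: a pure sine of amplitude A contributes
#' amplitude A at its frequency bin (2|DFT|/N, with the DC and Nyquist bins
#' unhalved). No window is applied by default, which is exact when the record
#' holds whole cycles; a Hann window is available for real recordings.
#'
#' @param s A [phyto_signal()].
#' @param detrend Remove the mean first (default `TRUE`).
#' @param window `"none"` (default) or `"hann"`.
#' @return An object of class `amplitude_spectrum`: list with `freqs` (Hz,
#'   0 to fs/2) and `amps` (volts), equal lengths.
#' @export
amplitude_spectrum <- function(s, detrend = TRUE,
                               window = c("none", "hann")) {
  stopifnot(inherits(s, "phyto_signal"))
  window <- match.arg(window)
  x <- s$samples
  if (detrend) x <- x - mean(x)
  n <- length(x)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    x <- x * w / mean(w)  # preserve sinusoid-amplitude reading
  }
  half <- n %/% 2L + 1L
  amps <- Mod(stats::fft(x)[seq_len(half)]) / n
  # double interior bins; DC (bin 1) and, for even n, Nyquist (bin half) stay
  dbl <- seq(2L, half - if (n %% 2L == 0L) 1L else 0L)
  amps[dbl] <- 2 * amps[dbl]
  structure(list(freqs = (seq_len(half) - 1L) * s$fs / n, amps = amps),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  i <- which.max(x$amps[-1]) + 1L
  cat(sprintf("<amplitude_spectrum> %d bins, df %.4g Hz, strongest line %.4g V at %.4g Hz\n",
              length(x$freqs), x$freqs[2] - x$freqs[1], x$amps[i], x$freqs[i]))
  invisible(x)
}

#' Characteristic sub-5 Hz frequency of a plant electrical signal
#'
#' Plant electrical signals carry their physiological information below 5 Hz;
#' the characteristic frequency is the argmax of the amplitude spectrum over
#' 0 < f <= `band_max` (DC excluded), reported at the bin centre.
#'
#' @param spec An [amplitude_spectrum()].
#' @param band_max Upper band edge, Hz.
#' @return A list of class `characteristic_peak` with `freq` (Hz) and `amp`
#'   (volts); both `NA` when the band is empty or identically zero.
#' @export
characteristic_frequency <- function(spec, band_max = 5) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  idx <- which(spec$freqs > 0 & spec$freqs <= band_max)
  if (!length(idx) || all(spec$amps[idx] == 0))
    return(structure(list(freq = NA_real_, amp = NA_real_),
                     class = "characteristic_peak"))
  i <- idx[which.max(spec$amps[idx])]
  structure(list(freq = spec$freqs[i], amp = spec$amps[i]),
            class = "characteristic_peak")
}

#' @export
print.characteristic_peak <- function(x, ...) {
  if (is.na(x$freq)) cat("<characteristic_peak> none found\n")
  else cat(sprintf("<characteristic_peak> %.4g Hz, amplitude %.4g V\n",
                   x$freq, x$amp))
  invisible(x)
}
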