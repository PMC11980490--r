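#' Parameters for the synthetic plant electrical-signal generator
#'
#' The generated signal is a fast carrier oscillation (the ~20 ms-period
#' fluctuation seen on amplified recordings) superposed with a slow sub-5 Hz
#' physiological component and white measurement noise:
#' \deqn{x(t) = \frac{A}{2}(1-f)\sin(2\pi f_c t) + \frac{A}{2} f \sin(2\pi f_s t) + \epsilon_t}
#' with `A = carrier_pp`, `f = slow_amp_fraction`, and
#' \eqn{\epsilon_t \sim N(0, noise\_sd^2)}.
#'
#' @param fs Sampling frequency, Hz.
#' @param duration Record length, seconds. The default 100 s gives a 0.01 Hz
#'   spectral resolution, so the 0.37 Hz slow component falls exactly on a
#'   Fourier bin.
#' @param carrier_freq Carrier frequency, Hz (default 50 Hz, i.e. 20 ms period).
#' @param carrier_pp Peak-to-peak amplitude of the deterministic part, volts.
#' @param slow_freq Slow-component frequency, Hz; must lie in (0, 5) and
#'   `duration * slow_freq` must be an integer (whole cycles in the record).
#' @param slow_amp_fraction Fraction of the deterministic amplitude carried by
#'   the slow component, in \[0, 1).
#' @param noise_sd Measurement-noise standard deviation, volts.
#' @param seed Integer seed.
#' @return An object of class `esignal_gen_params`.
#' @export
esignal_gen_params <- function(fs = 2000, duration = 100, carrier_freq = 50,
                               carrier_pp = 2, slow_freq = 0.37,
                               slow_amp_fraction = 0.1, noise_sd = 0.02,
                               seed = 1L) {
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive", call. = FALSE)
  if (fs <= 2 * carrier_freq)
    stop("fs must exceed twice the carrier frequency", call. = FALSE)
  if (slow_freq <= 0 || slow_freq >= 5)
    stop("slow_freq must lie in (0, 5) Hz", call. = FALSE)
  if (abs(duration * slow_freq - round(duration * slow_freq)) > 1e-9)
    stop("duration * slow_freq must be an integer (whole slow cycles)", call. = FALSE)
  if (slow_amp_fraction < 0 || slow_amp_fraction >= 1)
    stop("slow_amp_fraction must lie in [0, 1)", call. = FALSE)
  if (carrier_pp <= 0) stop("carrier_pp must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(fs = fs, duration = duration, carrier_freq = carrier_freq,
                 carrier_pp = carrier_pp, slow_freq = slow_freq,
                 slow_amp_fraction = slow_amp_fraction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "esignal_gen_params")
}

#' Construct an electrical-signal object
#'
#' @param samples Numeric vector of voltages.
#' @param fs Sampling frequency, Hz.
#' @return An object of class `phyto_signal`.
#' @export
phyto_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (length(samples) < 2L) stop("a signal needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(samples))) stop("signal samples must be finite", call. = FALSE)
  structure(list(samples = samples, fs = fs), class = "phyto_signal")
}

#' @export
print.phyto_signal <- function(x, ...) {
  cat(sprintf("<phyto_signal> %d samples @ %g Hz (%.3g s), range [%.4g, %.4g] V\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Generate a synthetic plant electrical signal
#'
#' @param params An [esignal_gen_params()] object.
#' @return A [phyto_signal()] with `fs * duration` samples.
#' @export
#' @examples
#' s <- generate_esignal(esignal_gen_params(duration = 10, carrier_pp = 5.008,
#'                                          slow_freq = 0.4, seed = 1))
#' signal_stats(s)$peak_v
generate_esignal <- function(params) {
  stopifnot(inherits(params, "esignal_gen_params"))
  n <- round(params$fs * params$duration)
  t <- (seq_len(n) - 1) / params$fs
  a <- params$carrier_pp / 2
  f <- params$slow_amp_fraction
  det <- a * (1 - f) * sin(2 * pi * params$carrier_freq * t) +
    a * f * sin(2 * pi * params$slow_freq * t)
  noise <- if (params$noise_sd > 0)
    withr::with_seed(params$seed, rnorm(n, 0, params$noise_sd))
  else rep(0, n)
  phyto_signal(det + noise, params$fs)
}
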