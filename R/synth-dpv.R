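#' Parameters for the synthetic differential pulse voltammogram generator
#'
#' The generated current is a linear baseline plus phenomenological Gaussian
#' redox peaks plus white noise:
#' \deqn{i(V) = b (V - V_{start}) + c \sum_k h_k
#'   \exp\!\left(-\frac{(V - p_k)^2}{2 (w_k / 2.3548)^2}\right) + \epsilon}
#' where `b` is `baseline_slope`, `c` is `concentration_scale` (peak current is
#' proportional to the concentration of the electroactive substance), and
#' `w_k` is the full width at half maximum of peak `k`.
#'
#' @param v_start,v_end Scan limits, volts; negative-going scan so
#'   `v_start > v_end` (defaults 0 and -1.5 V).
#' @param v_step Step potential magnitude, volts (default 5 mV, 301 samples).
#' @param peaks A data.frame with columns `position` (V, inside the scan
#'   range), `height` (uA, > 0) and `width` (V FWHM, > 0); may have zero rows.
#' @param baseline_slope Baseline slope, uA/V.
#' @param concentration_scale Unitless multiplier on all peak heights.
#' @param noise_sd Current-noise standard deviation, uA.
#' @param seed Integer seed.
#' @return An object of class `dpv_gen_params`.
#' @export
dpv_gen_params <- function(v_start = 0, v_end = -1.5, v_step = 0.005,
                           peaks = data.frame(position = numeric(0),
                                              height = numeric(0),
                                              width = numeric(0)),
                           baseline_slope = -2, concentration_scale = 1,
                           noise_sd = 0.05, seed = 1L) {
  if (v_start <= v_end) stop("negative-going scan requires v_start > v_end", call. = FALSE)
  if (v_step <= 0) stop("v_step must be positive", call. = FALSE)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("position", "height", "width") %in% names(peaks)))
  if (nrow(peaks)) {
    if (any(peaks$position <= v_end | peaks$position >= v_start))
      stop("all peak positions must lie inside (v_end, v_start)", call. = FALSE)
    if (any(peaks$height <= 0)) stop("peak heights must be positive", call. = FALSE)
    if (any(peaks$width <= 0)) stop("peak widths must be positive", call. = FALSE)
  }
  if (concentration_scale <= 0) stop("concentration_scale must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(v_start = v_start, v_end = v_end, v_step = v_step,
                 peaks = peaks, baseline_slope = baseline_slope,
                 concentration_scale = concentration_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dpv_gen_params")
}

#' Construct a voltammogram object
#'
#' @param potential Numeric vector of potentials, volts, strictly decreasing
#'   (negative-going scan).
#' @param current Numeric vector of currents, uA, same length.
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(potential, current) {
  potential <- as.numeric(potential); current <- as.numeric(current)
  if (length(potential) != length(current))
    stop("potential and current must have equal length", call. = FALSE)
  if (length(potential) < 10L)
    stop("a voltammogram needs at least 10 samples", call. = FALSE)
  if (any(diff(potential) >= 0))
    stop("potential must be strictly decreasing (negative-going scan)", call. = FALSE)
  if (any(!is.finite(potential)) || any(!is.finite(current)))
    stop("voltammogram values must be finite", call. = FALSE)
  structure(list(potential = potential, current = current),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("<voltammogram> %d points, %g to %g V, current [%.3g, %.3g] uA\n",
              length(x$potential), x$potential[1],
              x$potential[length(x$potential)],
              min(x$current), max(x$current)))
  invisible(x)
}

gaussian_peak_sum <- function(v, peaks, scale = 1) {
  out <- rep(0, length(v))
  for (k in seq_len(nrow(peaks))) {
    s <- peaks$width[k] / 2.3548
    out <- out + peaks$height[k] * exp(-(v - peaks$position[k])^2 / (2 * s^2))
  }
  scale * out
}

#' Generate a synthetic differential pulse voltammogram
#'
#' @param params A [dpv_gen_params()] object.
#' @return A [voltammogram()] sampled from `v_start` to `v_end` in `-v_step`
#'   increments.
#' @export
#' @examples
#' pk <- data.frame(position = c(-0.4, -0.9), height = c(10, 6),
#'                  width = c(0.1, 0.1))
#' v <- generate_dpv(dpv_gen_params(peaks = pk, noise_sd = 0))
#' detect_peaks(baseline_correct(v))
generate_dpv <- function(params) {
  stopifnot(inherits(params, "dpv_gen_params"))
  v <- seq(params$v_start, params$v_end, by = -params$v_step)
  cur <- params$baseline_slope * (v - params$v_start) +
    gaussian_peak_sum(v, params$peaks, params$concentration_scale)
  if (params$noise_sd > 0)
    cur <- cur + withr::with_seed(params$seed,
                                  rnorm(length(v), 0, params$noise_sd))
  voltammogram(v, cur)
}
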