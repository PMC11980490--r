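#' Parameters for the synthetic plant-image generator
#'
#' @param width,height Frame size in pixels.
#' @param n_foreground Exact number of plant (foreground) pixels to place.
#' @param channel_means Length-3 numeric, target R/G/B barycenters on the
#'   0--255 intensity axis.
#' @param channel_sds Length-3 numeric, per-channel intensity standard
#'   deviations (for a Gaussian channel histogram, FWHM = 2.3548 * sd).
#' @param background_level Background intensity (0--255); background-subtracted
#'   acquisitions use 0.
#' @param n_blobs Number of elliptical leaf blobs the foreground is split into.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `image_gen_params`.
#' @export
image_gen_params <- function(width = 640L, height = 400L, n_foreground,
                             channel_means, channel_sds,
                             background_level = 0L, n_blobs = 6L, seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  n_foreground <- as.numeric(n_foreground)
  stopifnot(length(channel_means) == 3L, length(channel_sds) == 3L)
  if (width < 1L || height < 1L) stop("frame must be at least 1x1", call. = FALSE)
  if (is.na(n_foreground) || n_foreground <= 0 ||
      n_foreground >= as.numeric(width) * height)
    stop("n_foreground must satisfy 0 < n_foreground < width*height",
         call. = FALSE)
  if (any(channel_means < 0 | channel_means > 255))
    stop("channel_means must lie in [0, 255]", call. = FALSE)
  if (any(channel_sds <= 0))
    stop("channel_sds must be positive", call. = FALSE)
  if (background_level < 0 || background_level > 255)
    stop("background_level must lie in [0, 255]", call. = FALSE)
  structure(list(width = width, height = height,
                 n_foreground = as.integer(round(n_foreground)),
                 channel_means = as.numeric(channel_means),
                 channel_sds = as.numeric(channel_sds),
                 background_level = as.integer(background_level),
                 n_blobs = as.integer(n_blobs), seed = as.integer(seed)),
            class = "image_gen_params")
}

#' Latent mean that calibrates a truncated, discretised channel to a target
#' barycenter
#'
#' Channel intensities are sampled from a normal truncated to the 8-bit range
#' and rounded to integer bins; the zero bin is excluded from downstream
#' features (background subtraction convention). Both effects bias the
#' zero-excluded histogram mean away from the latent normal mean, so the
#' generator solves for the latent mean whose *expected* zero-excluded
#' discretised barycenter equals the requested target.
#'
#' @param target Target barycenter (0--255 scale).
#' @param sd Latent normal standard deviation.
#' @return The latent mean to sample with.
#' @keywords internal
calibrate_channel_mean <- function(target, sd) {
  if (sd < 0.5) return(target)  # degenerate: rounding dominates, no bias
  expected_bary <- function(mu) {
    edges <- pnorm(seq(-0.5, 255.5, by = 1), mean = mu, sd = sd)
    p <- diff(edges)            # bin masses v = 0..255, truncation cancels
    v <- 0:255
    sum(v[-1] * p[-1]) / sum(p[-1])
  }
  f <- function(mu) expected_bary(mu) - target
  lo <- target - 4 * sd - 10
  hi <- min(target + 4 * sd + 10, 400)
  if (f(lo) > 0 || f(hi) < 0) return(target)  # no bracket: bias negligible
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

# Union-of-ellipses mask with exactly n pixels: pixels are ranked by the
# minimum normalised elliptical distance to a set of random blob centres and
# the n closest are selected (a level set of that field is a union of
# ellipses). Assumes the RNG state is already seeded.
blob_mask <- function(width, height, n, n_blobs) {
  cx <- runif(n_blobs, 0.2 * width, 0.8 * width)
  cy <- runif(n_blobs, 0.2 * height, 0.8 * height)
  aspect <- exp(runif(n_blobs, -0.5, 0.5))
  scale <- runif(n_blobs, 0.6, 1.4)
  x <- rep(seq_len(width), each = height)
  y <- rep(seq_len(height), times = width)
  pot <- rep(Inf, width * height)
  for (k in seq_len(n_blobs)) {
    d <- ((x - cx[k]) * aspect[k])^2 + ((y - cy[k]) / aspect[k])^2
    pot <- pmin(pot, d / scale[k])
  }
  sel <- order(pot)[seq_len(n)]   # deterministic tie-break by pixel index
  mask <- matrix(FALSE, nrow = height, ncol = width)
  mask[cbind(y[sel], x[sel])] <- TRUE
  mask
}

# Truncated-normal sample on (-0.5, 255.5) via inverse CDF, rounded to bins.
rtrunc8 <- function(n, mean, sd) {
  lo <- pnorm(-0.5, mean, sd)
  hi <- pnorm(255.5, mean, sd)
  round(qnorm(runif(n, lo, hi), mean, sd))
}

#' Generate a synthetic visible-light plant image with ground-truth mask
#'
#' Places `n_foreground` plant pixels (a union of elliptical leaf blobs) in a
#' uniform-background frame. Per-channel foreground intensities are drawn from
#' a normal distribution truncated to the 8-bit range, with the latent mean
#' calibrated (see [calibrate_channel_mean()]) so that the zero-excluded
#' channel barycenter recovers `channel_means` in expectation.
#'
#' @param params An [image_gen_params()] object.
#' @return A list of class `plant_image` with elements `image` (height x width
#'   x 3 integer array, values 0--255), `mask` (height x width logical,
#'   `TRUE` = plant) and `params`.
#' @export
#' @examples
#' p <- image_gen_params(width = 80, height = 50, n_foreground = 600,
#'                       channel_means = c(120, 155, 95),
#'                       channel_sds = c(20, 18, 22), seed = 42)
#' img <- generate_plant_image(p)
#' sum(img$mask)  # exactly 600
generate_plant_image <- function(params) {
  stopifnot(inherits(params, "image_gen_params"))
  withr::with_seed(params$seed, {
    mask <- blob_mask(params$width, params$height, params$n_foreground,
                      params$n_blobs)
    img <- array(params$background_level,
                 dim = c(params$height, params$width, 3L))
    n <- params$n_foreground
    for (ch in 1:3) {
      mu <- calibrate_channel_mean(params$channel_means[ch],
                                   params$channel_sds[ch])
      plane <- img[, , ch]
      plane[mask] <- rtrunc8(n, mu, params$channel_sds[ch])
      img[, , ch] <- plane
    }
    structure(list(image = img, mask = mask, params = params),
              class = "plant_image")
  })
}

#' @export
print.plant_image <- function(x, ...) {
  cat(sprintf("<plant_image> %dx%d px, %d foreground px (%.1f%%)\n",
              x$params$width, x$params$height, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}
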