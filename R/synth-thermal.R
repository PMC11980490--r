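#' Parameters for the synthetic thermal-image generator
#'
#' Emulates a thermal infrared canopy acquisition: a transpiring (hence
#' cooler) canopy of elliptical blobs over a warmer uniform background.
#'
#' @param width,height Frame size in pixels (nominal probe resolution 256x192).
#' @param canopy_mean Mean canopy temperature, degrees C; must be below
#'   `background_mean`.
#' @param canopy_sd Canopy temperature standard deviation, degrees C.
#' @param background_mean Background temperature, degrees C.
#' @param n_canopy Exact number of canopy pixels.
#' @param n_blobs Number of elliptical canopy blobs.
#' @param seed Integer seed.
#' @return An object of class `thermal_gen_params`.
#' @export
thermal_gen_params <- function(width = 256L, height = 192L, canopy_mean = 24,
                               canopy_sd = 0.8, background_mean = 30,
                               n_canopy = 12000L, n_blobs = 5L, seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  if (canopy_mean >= background_mean)
    stop("canopy_mean must be below background_mean (transpiring canopy is cooler)",
         call. = FALSE)
  if (canopy_sd < 0) stop("canopy_sd must be non-negative", call. = FALSE)
  if (n_canopy <= 0 || n_canopy >= as.numeric(width) * height)
    stop("n_canopy must satisfy 0 < n_canopy < width*height", call. = FALSE)
  structure(list(width = width, height = height, canopy_mean = canopy_mean,
                 canopy_sd = canopy_sd, background_mean = background_mean,
                 n_canopy = as.integer(n_canopy), n_blobs = as.integer(n_blobs),
                 seed = as.integer(seed)),
            class = "thermal_gen_params")
}

#' Generate a synthetic thermal canopy image with ground-truth mask
#'
#' @param params A [thermal_gen_params()] object.
#' @return A list of class `thermal_image` with elements `temps` (height x
#'   width numeric matrix, degrees C), `mask` (logical, `TRUE` = canopy) and
#'   `params`.
#' @export
generate_thermal_image <- function(params) {
  stopifnot(inherits(params, "thermal_gen_params"))
  withr::with_seed(params$seed, {
    mask <- blob_mask(params$width, params$height, params$n_canopy,
                      params$n_blobs)
    temps <- matrix(params$background_mean,
                    nrow = params$height, ncol = params$width)
    temps[mask] <- rnorm(params$n_canopy, params$canopy_mean, params$canopy_sd)
    structure(list(temps = temps, mask = mask, params = params),
              class = "thermal_image")
  })
}

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf("<thermal_image> %dx%d px, %d canopy px, canopy mean %.2f C\n",
              ncol(x$temps), nrow(x$temps), sum(x$mask),
              mean(x$temps[x$mask])))
  invisible(x)
}
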