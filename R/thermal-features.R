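#' Canopy temperature statistics from a thermal raster
#'
#' Computes the mean and minimum canopy temperature and the fraction of canopy
#' pixels in the "low temperature region". The low-temperature threshold
#' defaults to the background median minus 2 degrees C (a scene-relative
#' definition, robust across acquisitions); an absolute threshold can be given
#' instead for cross-scene comparability.
#'
#' @param temps Height x width numeric matrix of temperatures (degrees C), or
#'   a `thermal_image`.
#' @param mask Logical canopy mask; defaults to the ground-truth mask of a
#'   `thermal_image`.
#' @param abs_threshold Optional absolute low-temperature threshold, degrees C;
#'   overrides the relative rule.
#' @param rel_offset Offset below the background median used by the relative
#'   rule, degrees C.
#' @return A list of class `thermal_summary` with `canopy_mean`, `canopy_min`,
#'   `low_temp_fraction` and `threshold_used`.
#' @export
#' @examples
#' t <- generate_thermal_image(thermal_gen_params(seed = 3))
#' canopy_stats(t)
canopy_stats <- function(temps, mask = NULL, abs_threshold = NULL,
                         rel_offset = 2) {
  if (inherits(temps, "thermal_image")) {
    if (is.null(mask)) mask <- temps$mask
    temps <- temps$temps
  }
  stopifnot(is.matrix(temps), !is.null(mask), all(dim(mask) == dim(temps)))
  if (!any(mask)) stop("undefined feature: empty canopy mask", call. = FALSE)
  canopy <- temps[mask]
  threshold <- if (!is.null(abs_threshold)) abs_threshold else {
    bg <- temps[!mask]
    if (!length(bg))
      stop("mask covers the whole frame; supply abs_threshold", call. = FALSE)
    median(bg) - rel_offset
  }
  structure(list(canopy_mean = mean(canopy),
                 canopy_min = min(canopy),
                 low_temp_fraction = mean(canopy < threshold),
                 threshold_used = threshold),
            class = "thermal_summary")
}

#' @export
print.thermal_summary <- function(x, ...) {
  cat(sprintf("<thermal_summary> mean %.2f C, min %.2f C, %.1f%% below %.2f C\n",
              x$canopy_mean, x$canopy_min, 100 * x$low_temp_fraction,
              x$threshold_used))
  invisible(x)
}

#' Thermal-only canopy segmentation
#'
#' When no co-registered visible-image mask exists, the canopy is segmented
#' from the temperature raster alone by an Otsu split of its value
#' distribution; the cooler class is taken as the transpiring canopy.
#'
#' @param temps Height x width numeric matrix (degrees C).
#' @return Logical mask (`TRUE` = canopy).
#' @export
segment_thermal <- function(temps) {
  if (inherits(temps, "thermal_image")) temps <- temps$temps
  stopifnot(is.matrix(temps))
  rng <- range(temps)
  if (diff(rng) <= 0) return(matrix(FALSE, nrow(temps), ncol(temps)))
  norm <- (temps - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  temps < rng[1] + thr * diff(rng)
}
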