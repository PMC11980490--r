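#' Segment the plant from a background-subtracted image
#'
#' A pixel is foreground when the largest per-channel distance from the
#' background level exceeds `tol`; connected components smaller than
#' `min_component` pixels are then discarded as noise.
#'
#' @param image Height x width x 3 array of 8-bit intensities, or a
#'   `plant_image`.
#' @param bg_level Background intensity (0 for background-subtracted images).
#' @param tol Intensity tolerance; with `tol = 0` every pixel differing from
#'   `bg_level` in any channel is selected (before the area filter).
#' @param min_component Minimum connected-component area in pixels.
#' @return Height x width logical mask (`TRUE` = plant). An empty mask is
#'   legal.
#' @export
segment_plant <- function(image, bg_level = 0, tol = 10, min_component = 16L) {
  if (inherits(image, "plant_image")) image <- image$image
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  d <- pmax(abs(image[, , 1] - bg_level),
            abs(image[, , 2] - bg_level),
            abs(image[, , 3] - bg_level))
  mask <- d > tol
  if (!any(mask) || min_component <= 1L) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component)
  matrix(lab %in% keep, nrow = nrow(mask))
}

#' Per-channel intensity histogram of the segmented plant
#'
#' @param image Height x width x 3 array of 8-bit intensities, or a
#'   `plant_image`.
#' @param mask Logical mask of the same frame size.
#' @param channel `"R"`, `"G"` or `"B"` (or 1--3).
#' @return An object of class `channel_histogram`: list with `counts`
#'   (integer vector of length 256 for intensities 0--255) and `channel`.
#' @export
channel_histogram <- function(image, mask, channel) {
  if (inherits(image, "plant_image")) image <- image$image
  if (is.character(channel)) channel <- match(channel, c("R", "G", "B"))
  stopifnot(channel %in% 1:3, all(dim(mask) == dim(image)[1:2]))
  vals <- image[, , channel][mask]
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  structure(list(counts = counts, channel = c("R", "G", "B")[channel]),
            class = "channel_histogram")
}

#' @export
print.channel_histogram <- function(x, ...) {
  cat(sprintf("<channel_histogram> %s: %d px (%d at zero)\n",
              x$channel, sum(x$counts), x$counts[1]))
  invisible(x)
}

#' Histogram integral area (pixel count, zero bin excluded)
#'
#' Intensity 0 is excluded throughout the feature computations: background
#' subtraction zeroes the background, so zero-valued pixels are
#' indistinguishable from it. This per-channel exclusion is also why the
#' per-channel integral areas of one image can differ slightly.
#'
#' @param h A [channel_histogram()].
#' @return Number of contributing pixels with intensity 1--255.
#' @export
integral_area <- function(h) {
  stopifnot(inherits(h, "channel_histogram"))
  sum(h$counts[-1])
}

#' Histogram barycenter (intensity-weighted mean, zero bin excluded)
#'
#' @param h A [channel_histogram()].
#' @return Barycenter on the 0--255 intensity axis.
#' @export
barycenter <- function(h) {
  stopifnot(inherits(h, "channel_histogram"))
  n <- sum(h$counts[-1])
  if (n == 0) stop("undefined feature: empty histogram", call. = FALSE)
  sum((1:255) * h$counts[-1]) / n
}

#' Histogram full width at half maximum
#'
#' Counts are smoothed with a centered moving average (real channel
#' histograms are ragged), the global maximum over intensities 1--255 is
#' located, and the nearest half-maximum crossings left and right of the
#' maximum are found by linear interpolation between adjacent bins.
#'
#' @param h A [channel_histogram()].
#' @param smooth_window Moving-average window in bins (default 5; use 1 for
#'   no smoothing). Must be odd.
#' @return FWHM in intensity units. If the peak sits at a boundary with no
#'   crossing on one side, the one-sided width is doubled and the result
#'   carries attribute `one_sided = TRUE`.
#' @export
fwhm <- function(h, smooth_window = 5L) {
  stopifnot(inherits(h, "channel_histogram"))
  if (sum(h$counts[-1]) == 0)
    stop("undefined feature: empty histogram", call. = FALSE)
  w <- as.integer(smooth_window)
  stopifnot(w >= 1L, w %% 2L == 1L)
  y <- as.numeric(h$counts)
  if (w > 1L) {
    k <- (w - 1L) %/% 2L
    padded <- c(rep(0, k), y, rep(0, k))
    y <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[(k + 1L):(k + 256L)]
  }
  # v = 0..255 maps to index v+1; global max restricted to v >= 1
  peak <- which.max(y[-1]) + 1L
  half <- y[peak] / 2
  cross <- function(dir) {
    j <- peak
    repeat {
      j2 <- j + dir
      if (j2 < 2L || j2 > 256L) return(NA_real_)  # stay within v = 1..255
      if (y[j2] < half) {
        # interpolate between bins j (>= half) and j2 (< half)
        frac <- (y[j] - half) / (y[j] - y[j2])
        return((j - 1L) + dir * frac)
      }
      j <- j2
    }
  }
  left <- cross(-1L); right <- cross(+1L)
  if (is.na(left) && is.na(right))
    stop("undefined feature: no half-maximum crossing on either side", call. = FALSE)
  if (is.na(left) || is.na(right)) {
    side <- if (is.na(left)) right - (peak - 1L) else (peak - 1L) - left
    return(structure(2 * side, one_sided = TRUE))
  }
  right - left
}

#' Green dominance from channel barycenters
#'
#' GD = G / (R + G + B), computed on the per-channel histogram barycenters; a
#' proxy for leaf greenness (chlorophyll retention) that is insensitive to
#' plant size.
#'
#' @param r_bary,g_bary,b_bary Channel barycenters, all positive.
#' @return GD as a unitless fraction in (0, 1).
#' @export
#' @examples
#' round(100 * green_dominance(122.18904, 155.77954, 94.29842), 1)  # 41.8
green_dominance <- function(r_bary, g_bary, b_bary) {
  if (any(c(r_bary, g_bary, b_bary) <= 0) || !all(is.finite(c(r_bary, g_bary, b_bary))))
    stop("undefined feature: barycenters must be positive", call. = FALSE)
  g_bary / (r_bary + g_bary + b_bary)
}

#' Full per-image feature record
#'
#' Composes segmentation-independent channel features into one record: per
#' channel the integral area, barycenter and FWHM, plus green dominance.
#'
#' @param image Height x width x 3 array (or `plant_image`).
#' @param mask Logical mask; when omitted and `image` is a `plant_image`, its
#'   ground-truth mask is used.
#' @param smooth_window FWHM smoothing window, bins.
#' @return A one-row data.frame with columns `r_area`, `r_bary`, `r_fwhm`,
#'   `g_area`, ..., `b_fwhm`, `gd` and a logical `defined` flag. With an empty
#'   mask all features are `NA` and `defined` is `FALSE`.
#' @export
image_feature_row <- function(image, mask = NULL, smooth_window = 5L) {
  if (is.null(mask)) {
    stopifnot(inherits(image, "plant_image"))
    mask <- image$mask
  }
  out <- data.frame(r_area = NA_real_, r_bary = NA_real_, r_fwhm = NA_real_,
                    g_area = NA_real_, g_bary = NA_real_, g_fwhm = NA_real_,
                    b_area = NA_real_, b_bary = NA_real_, b_fwhm = NA_real_,
                    gd = NA_real_, defined = FALSE)
  if (!any(mask)) return(out)
  bary <- numeric(3)
  for (ch in 1:3) {
    h <- channel_histogram(image, mask, ch)
    if (integral_area(h) == 0) return(out)
    pre <- c("r", "g", "b")[ch]
    out[[paste0(pre, "_area")]] <- integral_area(h)
    bary[ch] <- barycenter(h)
    out[[paste0(pre, "_bary")]] <- bary[ch]
    out[[paste0(pre, "_fwhm")]] <- as.numeric(fwhm(h, smooth_window))
  }
  out$gd <- green_dominance(bary[1], bary[2], bary[3])
  out$defined <- TRUE
  out
}
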