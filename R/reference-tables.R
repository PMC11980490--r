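#' Reference RGB decomposition features for the pepper drought study
#'
#' Published reference values of the per-channel histogram features (integral
#' area in pixels, barycenter and FWHM on the 0--255 intensity axis) of
#' background-subtracted visible-light images of pepper plants, across the
#' three soil treatments (`original`, `biochar2` = +2\% biochar, `biochar4` =
#' +4\% biochar) and four drought timepoints (day 0, 2, 4, 6). These values
#' calibrate the synthetic image generator and provide the barycenters from
#' which the green-dominance benchmarks are computed.
#'
#' @return A data.frame with columns `treatment`, `day`, `channel`
#'   (`"R"`, `"G"`, `"B"`), `integral_area`, `barycenter`, `fwhm`.
#' @seealso [green_dominance()], [default_image_params()]
#' @export
#' @examples
#' ref <- rgb_reference()
#' subset(ref, treatment == "original" & day == 0)
rgb_reference <- function() {
  # rows: treatment, day, R(area, bary, fwhm), G(...), B(...)
  raw <- list(
    list("original", 0L, 915796,   122.18904, 93.23168,  915796,   155.77954, 84.60555,  915458,   94.29842,  98.2579),
    list("original", 2L, 887883,   138.79981, 115.00513, 887864,   169.83324, 96.89384,  886418.5, 105.1517,  109.34467),
    list("original", 4L, 637264,   144.67628, 108.57516, 637264,   173.1801,  91.77886,  637150,   111.03414, 103.68584),
    list("original", 6L, 245341,   161.17829, 95.70155,  245341,   183.06305, 89.72863,  245341,   119.85221, 95.01087),
    list("biochar2", 0L, 687753,   144.34983, 95.12128,  687753,   172.97689, 75.82036,  687753,   118.78648, 100.03365),
    list("biochar2", 2L, 816240,   144.50834, 121.39686, 816195,   174.13671, 109.73123, 815151.5, 103.79222, 101.04725),
    list("biochar2", 4L, 653911,   152.72323, 110.62883, 653869.5, 183.379,   103.20266, 653015,   108.74241, 88.57322),
    list("biochar2", 6L, 401992,   150.13314, 100.86988, 401970,   180.50439, 89.10542,  401523.5, 95.62488,  95.62488),
    list("biochar4", 0L, 700058,   121.14169, 79.02095,  700058,   148.35304, 65.32253,  700052,   96.80462,  80.70043),
    list("biochar4", 2L, 562509,   155.28203, 113.66721, 562498,   181.07274, 83.7965,   562439.5, 121.40066, 122.98113),
    list("biochar4", 4L, 516613,   151.06924, 104.62971, 516585.5, 179.01571, 88.87418,  516359,   107.52033, 98.9389),
    list("biochar4", 6L, 521343.5, 143.8908,  112.02855, 521321.5, 174.94072, 100.00407, 520648,   105.60115, 124.34274)
  )
  out <- do.call(rbind, lapply(raw, function(r) {
    data.frame(
      treatment = r[[1]], day = r[[2]],
      channel = c("R", "G", "B"),
      integral_area = c(r[[3]], r[[6]], r[[9]]),
      barycenter = c(r[[4]], r[[7]], r[[10]]),
      fwhm = c(r[[5]], r[[8]], r[[11]]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Reference electrical-signal statistics for the pepper drought study
#'
#' Published reference amplitude statistics of the amplified plant
#' electrical-signal recordings: maximum, minimum, peak-to-peak value (volts)
#' and oscillation period (milliseconds) for each (treatment, day) cell.
#' These values calibrate the synthetic signal generator (the per-cell
#' peak-to-peak target and carrier period).
#'
#' A few rows are internally inconsistent at the printed precision
#' (peak value differs from max - min in the last digit); `self_consistent`
#' flags the rows where `peak_v == max_v - min_v` exactly at 3 decimals.
#'
#' @return A data.frame with columns `treatment`, `day`, `max_v`, `min_v`,
#'   `peak_v`, `period_ms`, `self_consistent`.
#' @seealso [signal_stats()], [default_esignal_params()]
#' @export
esignal_reference <- function() {
  out <- data.frame(
    treatment = rep(c("original", "biochar2", "biochar4"), each = 4L),
    day = rep(c(0L, 2L, 4L, 6L), times = 3L),
    max_v = c(1.063, 1.648, 1.744, 2.396,
              0.867, 1.361, 1.851, 1.633,
              0.607, 1.143, 1.034, 1.470),
    min_v = c(-1.193, -1.560, -1.744, -2.612,
              -0.889, -1.415, -2.014, -1.633,
              -0.607, -1.198, -1.143, -1.579),
    peak_v = c(2.255, 3.208, 3.484, 5.008,
               1.756, 2.776, 3.865, 3.266,
               1.214, 2.341, 2.178, 3.049),
    period_ms = c(19.714, 20.000, 20.000, 20.000,
                  19.958, 20.000, 20.000, 20.000,
                  19.667, 20.000, 19.958, 20.000),
    stringsAsFactors = FALSE
  )
  out$self_consistent <- abs((out$max_v - out$min_v) - out$peak_v) < 5e-4
  out
}

#' Treatments and drought days of the study grid
#'
#' @return `study_treatments()`: the three soil treatment labels.
#'   `study_days()`: the four drought timepoints in days.
#' @export
study_treatments <- function() c("original", "biochar2", "biochar4")

#' @rdname study_treatments
#' @export
study_days <- function() c(0L, 2L, 4L, 6L)

check_condition <- function(treatment, day) {
  if (!treatment %in% study_treatments())
    stop("unknown treatment: ", treatment, call. = FALSE)
  if (!day %in% study_days())
    stop("day must be one of 0, 2, 4, 6; got ", day, call. = FALSE)
  invisible(NULL)
}
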