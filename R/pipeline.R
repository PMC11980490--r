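report_columns <- function() {
  c("treatment", "day",
    "r_area", "r_bary", "r_fwhm", "g_area", "g_bary", "g_fwhm",
    "b_area", "b_bary", "b_fwhm", "gd",
    "canopy_mean_C", "canopy_min_C", "low_temp_fraction",
    "max_v", "min_v", "peak_v", "period_ms", "char_freq_hz", "char_amp_v",
    "n_peaks", "mean_resolution", "overlap_flag", "total_peak_current",
    "complete")
}

na_row <- function(treatment, day) {
  out <- as.data.frame(as.list(setNames(rep(NA_real_, length(report_columns())),
                                        report_columns())))
  out$treatment <- treatment; out$day <- day
  out$overlap_flag <- NA; out$complete <- FALSE
  out
}

analyze_cell <- function(dir, paths, treatment, day, bg_level, tol) {
  row <- na_row(treatment, day)
  p <- function(mod) {
    i <- which(paths$modality == mod)
    if (length(i) != 1L) return(NULL)
    fp <- file.path(dir, paths$path[i])
    if (!file.exists(fp)) return(NULL)
    fp
  }
  ok <- TRUE

  img_path <- p("image")
  if (is.null(img_path)) ok <- FALSE else {
    img <- read_rgb_image(img_path)
    mask_path <- p("image_mask")
    mask <- if (!is.null(mask_path)) read_mask_png(mask_path)
            else segment_plant(img, bg_level = bg_level, tol = tol)
    feats <- image_feature_row(img, mask)
    for (cn in setdiff(names(feats), "defined")) row[[cn]] <- feats[[cn]]
    if (!feats$defined) ok <- FALSE
  }

  th_path <- p("thermal")
  if (is.null(th_path)) ok <- FALSE else {
    temps <- read_thermal(th_path)
    cs <- canopy_stats(temps, segment_thermal(temps))
    row$canopy_mean_C <- cs$canopy_mean
    row$canopy_min_C <- cs$canopy_min
    row$low_temp_fraction <- cs$low_temp_fraction
  }

  sig_path <- p("esignal")
  if (is.null(sig_path)) ok <- FALSE else {
    sig <- read_signal_csv(sig_path)
    st <- signal_stats(sig)
    row$max_v <- st$max_v; row$min_v <- st$min_v; row$peak_v <- st$peak_v
    row$period_ms <- st$period_ms
    cp <- characteristic_frequency(amplitude_spectrum(sig))
    row$char_freq_hz <- cp$freq; row$char_amp_v <- cp$amp
  }

  dpv_path <- p("dpv")
  if (is.null(dpv_path)) ok <- FALSE else {
    pk <- detect_peaks(baseline_correct(read_voltammogram_csv(dpv_path)))
    cl <- clarity(pk)
    row$n_peaks <- cl$n_peaks
    row$mean_resolution <- cl$mean_resolution
    row$overlap_flag <- cl$overlap_flag
    row$total_peak_current <- cl$total_peak_current
  }

  row$complete <- ok
  row
}

#' Run the full multi-modal study analysis
#'
#' Reads a study directory written by [generate_study()] (or real data
#' following the same manifest schema), runs every per-modality analyzer,
#' joins the results on (treatment, day) and returns the study report.
#' Visible images are segmented with the package's background-distance rule
#' unless a mask file is provided in the manifest; thermal rasters are
#' segmented with the Otsu split (the two modalities are not co-registered).
#'
#' @param input_dir Directory containing `manifest.csv` and the data files.
#' @param out_dir Optional output directory for `report.csv`, `trends.csv`
#'   and, with `plots = TRUE`, per-feature trend plots (PNG).
#' @param bg_level,tol Segmentation parameters for visible images without an
#'   external mask.
#' @param strict Fail (error) when any cell is incomplete instead of flagging
#'   it.
#' @param plots Write simple feature-versus-day plots.
#' @return A list of class `study_report` with `features` (one row per
#'   (treatment, day), `complete` flag per row) and `trends` (per-treatment
#'   least-squares day-slopes, see [trend_summary()]).
#' @export
run_study <- function(input_dir, out_dir = NULL, bg_level = 0, tol = 10,
                      strict = FALSE, plots = FALSE) {
  manifest <- read.csv(file.path(input_dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  cells <- unique(manifest[, c("treatment", "day")])
  cells <- cells[order(match(cells$treatment, study_treatments()), cells$day), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- cells$treatment[i]; dy <- cells$day[i]
    analyze_cell(input_dir,
                 manifest[manifest$treatment == tr & manifest$day == dy, ],
                 tr, dy, bg_level, tol)
  })
  features <- do.call(rbind, rows)[, report_columns()]
  rownames(features) <- NULL
  if (strict && !all(features$complete))
    stop("incomplete cells: ",
         paste(sprintf("(%s, day %d)", features$treatment[!features$complete],
                       features$day[!features$complete]), collapse = ", "),
         call. = FALSE)
  trends <- trend_summary(features)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(features, file.path(out_dir, "report.csv"), row.names = FALSE)
    write.csv(trends, file.path(out_dir, "trends.csv"), row.names = FALSE)
    if (plots) plot_trends(features, out_dir)
  }
  structure(list(features = features, trends = trends),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d cells (%d complete)\n",
              nrow(x$features), sum(x$features$complete)))
  print(x$features[, c("treatment", "day", "gd", "canopy_mean_C", "peak_v",
                       "total_peak_current", "overlap_flag")])
  invisible(x)
}

#' Per-treatment least-squares day trends
#'
#' The study's qualitative claims are endpoint comparisons; the report
#' quantifies each feature's trajectory as the least-squares slope of feature
#' versus drought day within each treatment, alongside the day-0 and day-6
#' endpoint values.
#'
#' @param features A feature table with columns `treatment`, `day` and the
#'   trended features (`gd`, `peak_v`, `canopy_mean_C`, `total_peak_current`).
#' @param trend_features Character vector of feature columns to trend.
#' @return A data.frame with one row per (treatment, feature): `slope` (per
#'   day; `NA` with fewer than 2 defined timepoints), `first` and `last`
#'   endpoint values.
#' @export
trend_summary <- function(features,
                          trend_features = c("gd", "peak_v", "canopy_mean_C",
                                             "total_peak_current")) {
  trend_features <- intersect(trend_features, names(features))
  out <- list()
  for (tr in unique(features$treatment)) {
    sub <- features[features$treatment == tr, ]
    sub <- sub[order(sub$day), ]
    for (f in trend_features) {
      y <- sub[[f]]; d <- sub$day
      keep <- !is.na(y)
      slope <- if (sum(keep) >= 2L)
        unname(coef(lm(y[keep] ~ d[keep]))[2]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, feature = f, slope = slope,
        first = y[keep][1L],
        last = if (any(keep)) y[keep][sum(keep)] else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

plot_trends <- function(features, out_dir,
                        cols = c("gd", "peak_v", "canopy_mean_C",
                                 "total_peak_current")) {
  for (f in intersect(cols, names(features))) {
    grDevices::png(file.path(out_dir, paste0("trend_", f, ".png")),
                   width = 640, height = 480)
    tr <- study_treatments()
    ylim <- range(features[[f]], na.rm = TRUE)
    graphics::plot(NA, xlim = range(features$day), ylim = ylim,
                   xlab = "drought day", ylab = f,
                   main = paste(f, "vs drought day"))
    for (i in seq_along(tr)) {
      sub <- features[features$treatment == tr[i], ]
      sub <- sub[order(sub$day), ]
      graphics::lines(sub$day, sub[[f]], type = "b", col = i, pch = i)
    }
    graphics::legend("topleft", legend = tr, col = seq_along(tr),
                     pch = seq_along(tr), lty = 1, bty = "n")
    grDevices::dev.off()
  }
  invisible(NULL)
}
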