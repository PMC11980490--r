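#' Default generator parameters for one study cell
#'
#' The synthetic study emulates the 3-treatment x 4-day acquisition grid.
#' Image and electrical-signal generators are calibrated cell-by-cell to the
#' published reference feature tables ([rgb_reference()],
#' [esignal_reference()]): channel means are the reference barycenters,
#' channel sds are reference FWHM / 2.3548, foreground counts are the largest
#' per-channel integral area (scaled down by `scale_down` for desk-scale
#' runtime), the signal peak-to-peak is the reference peak value and the
#' carrier frequency is 1000 / reference period. Thermal means and the DPV
#' peak sets have no published numeric counterpart and follow the documented
#' qualitative calibration (biochar: cooler canopy, higher electroactive
#' concentration; original-soil drought: warmer canopy, broadening and
#' drifting DPV peaks).
#'
#' @param treatment One of `"original"`, `"biochar2"`, `"biochar4"`.
#' @param day Drought day, one of 0, 2, 4, 6.
#' @param scale_down Divisor applied to the reference foreground pixel counts
#'   (default 10; use 1 for full-frame 1280x800 images).
#' @param seed Integer seed for the cell.
#' @return The corresponding `*_gen_params` object.
#' @name study_defaults
NULL

#' @rdname study_defaults
#' @export
default_image_params <- function(treatment, day, scale_down = 10, seed = 1L) {
  check_condition(treatment, day)
  ref <- rgb_reference()
  row <- ref[ref$treatment == treatment & ref$day == day, ]
  row <- row[match(c("R", "G", "B"), row$channel), ]
  full <- scale_down < 4
  image_gen_params(
    width = if (full) 1280L else 640L,
    height = if (full) 800L else 400L,
    n_foreground = round(max(row$integral_area) / scale_down),
    channel_means = row$barycenter,
    channel_sds = row$fwhm / 2.3548,
    background_level = 0L,
    seed = seed
  )
}

#' @rdname study_defaults
#' @export
default_thermal_params <- function(treatment, day, seed = 1L) {
  check_condition(treatment, day)
  base <- c(original = 23, biochar2 = 22.5, biochar4 = 22)
  rate <- c(original = 0.9, biochar2 = 0.45, biochar4 = 0.25)  # degC per day
  thermal_gen_params(canopy_mean = base[[treatment]] + rate[[treatment]] * day,
                     canopy_sd = 0.8, background_mean = 30,
                     n_canopy = 12000L, seed = seed)
}

#' @rdname study_defaults
#' @export
default_esignal_params <- function(treatment, day, seed = 1L) {
  check_condition(treatment, day)
  ref <- esignal_reference()
  row <- ref[ref$treatment == treatment & ref$day == day, ]
  esignal_gen_params(
    fs = 2000, duration = 100,
    carrier_freq = 1000 / row$period_ms,
    carrier_pp = row$peak_v,
    slow_freq = 0.37,
    slow_amp_fraction = c(`0` = 0.05, `2` = 0.10, `4` = 0.15, `6` = 0.20)[[as.character(day)]],
    noise_sd = 0.02, seed = seed
  )
}

#' @rdname study_defaults
#' @export
default_dpv_params <- function(treatment, day, seed = 1L) {
  check_condition(treatment, day)
  heights <- c(10, 10, 7)
  if (treatment == "original") {
    # drought destabilises the fingerprint: widths broaden 20% per two days
    # and the first peak drifts toward the second, so adjacent-peak
    # resolution Rs crosses 1 between day 2 and day 4
    gap1 <- c(`0` = 0.30, `2` = 0.24, `4` = 0.20, `6` = 0.19)[[as.character(day)]]
    width <- 0.10 * 1.2^(day / 2)
    pos <- c(-0.70 + gap1, -0.70, -1.10)
    # small seeded jitter of the isolated third peak (electrochemical
    # instability); the overlapping pair geometry is kept deterministic
    pos[3] <- pos[3] + withr::with_seed(seed + 7L,
                                        rnorm(1, 0, 0.005 * day / 2))
    conc <- 1.0
  } else {
    pos <- c(-0.40, -0.70, -1.10)
    width <- 0.10
    conc <- if (treatment == "biochar2") 1.3 else 1.6
  }
  dpv_gen_params(
    peaks = data.frame(position = pos, height = heights,
                       width = rep(width, 3)),
    baseline_slope = -2, concentration_scale = conc,
    noise_sd = 0.05, seed = seed
  )
}

#' Default configuration for a full synthetic study
#'
#' @param scale_down Foreground-count divisor for image generation.
#' @param esignal_duration Signal record length, seconds.
#' @return A list of class `study_config` with the study grid and per-modality
#'   settings; accepted by [generate_study()] and serialisable to YAML.
#' @export
default_study_config <- function(scale_down = 10, esignal_duration = 100) {
  structure(list(scale_down = scale_down,
                 esignal_duration = esignal_duration),
            class = "study_config")
}

#' @rdname default_study_config
#' @param path YAML file path.
#' @param config A `study_config` list.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_study_config()
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  cfg
}

#' @rdname default_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

study_grid <- function() {
  expand.grid(treatment = study_treatments(), day = study_days(),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, c("treatment", "day")]
}

#' Generate and write a full synthetic study to disk
#'
#' Writes, for every (treatment, day) cell of the 3x4 grid: an RGB plant image
#' (PNG) with its ground-truth mask (PNG), a thermal raster (CSV, degrees C)
#' with its mask (CSV), an electrical-signal recording (CSV: `time_s`,
#' `voltage_V`) and a voltammogram (CSV: `potential_V`, `current_uA`), plus a
#' `manifest.csv` (columns `treatment`, `day`, `modality`, `path`, `seed`).
#' Output is deterministic for a fixed `seed`: rerunning produces
#' byte-identical CSV files.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [default_study_config()] list.
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return Invisibly, the manifest data.frame.
#' @export
generate_study <- function(out_dir, config = default_study_config(),
                           seed = 1L) {
  grid <- study_grid()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  for (d in c("images", "thermal", "esignal", "dpv"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  cell_seeds <- withr::with_seed(as.integer(seed),
                                 sample.int(.Machine$integer.max %/% 2,
                                            4L * nrow(grid)))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    tr <- grid$treatment[i]; dy <- grid$day[i]
    tag <- sprintf("%s_day%d", tr, dy)
    sd4 <- cell_seeds[(i - 1L) * 4L + 1:4]

    img <- generate_plant_image(default_image_params(tr, dy,
                                                     config$scale_down, sd4[1]))
    img_path <- file.path("images", paste0(tag, ".png"))
    mask_path <- file.path("images", paste0(tag, "_mask.png"))
    png::writePNG(img$image / 255, file.path(out_dir, img_path))
    png::writePNG(img$mask * 1, file.path(out_dir, mask_path))

    th <- generate_thermal_image(default_thermal_params(tr, dy, sd4[2]))
    th_path <- file.path("thermal", paste0(tag, ".csv"))
    thm_path <- file.path("thermal", paste0(tag, "_mask.csv"))
    write.table(th$temps, file.path(out_dir, th_path), sep = ",",
                row.names = FALSE, col.names = FALSE)
    write.table(th$mask * 1L, file.path(out_dir, thm_path), sep = ",",
                row.names = FALSE, col.names = FALSE)

    ep <- default_esignal_params(tr, dy, sd4[3])
    ep$duration <- config$esignal_duration
    sig <- generate_esignal(ep)
    sig_path <- file.path("esignal", paste0(tag, ".csv"))
    write_signal_csv(sig, file.path(out_dir, sig_path))

    dpv <- generate_dpv(default_dpv_params(tr, dy, sd4[4]))
    dpv_path <- file.path("dpv", paste0(tag, ".csv"))
    write_voltammogram_csv(dpv, file.path(out_dir, dpv_path))

    rows[[i]] <- data.frame(
      treatment = tr, day = dy,
      modality = c("image", "image_mask", "thermal", "thermal_mask",
                   "esignal", "dpv"),
      path = c(img_path, mask_path, th_path, thm_path, sig_path, dpv_path),
      seed = c(sd4[1], sd4[1], sd4[2], sd4[2], sd4[3], sd4[4]),
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
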