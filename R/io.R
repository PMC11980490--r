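#' Read and write pipeline file formats
#'
#' Signals are 2-column CSVs (`time_s`, `voltage_V`); voltammograms are
#' 2-column CSVs (`potential_V`, `current_uA`); thermal rasters are headerless
#' CSV matrices in degrees C (32-bit float TIFF also readable when the tiff
#' package is available); images and masks are 8-bit PNG.
#'
#' @param path File path.
#' @param sig A [phyto_signal()].
#' @param v A [voltammogram()].
#' @name phyto_io
NULL

#' @rdname phyto_io
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "phyto_signal"))
  n <- length(sig$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / sig$fs,
                   voltage_V = sig$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname phyto_io
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path, colClasses = "numeric")
  stopifnot(all(c("time_s", "voltage_V") %in% names(df)))
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  phyto_signal(df$voltage_V, fs = 1 / median(dt))
}

#' @rdname phyto_io
#' @export
write_voltammogram_csv <- function(v, path) {
  stopifnot(inherits(v, "voltammogram"))
  write.csv(data.frame(potential_V = v$potential, current_uA = v$current),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname phyto_io
#' @export
read_voltammogram_csv <- function(path) {
  df <- read.csv(path, colClasses = "numeric")
  stopifnot(all(c("potential_V", "current_uA") %in% names(df)))
  voltammogram(df$potential_V, df$current_uA)
}

#' @rdname phyto_io
#' @export
read_rgb_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  else stop("expected a 3-channel PNG image", call. = FALSE)
  array(as.integer(round(x * 255)), dim = dim(x))
}

#' @rdname phyto_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' @rdname phyto_io
#' @export
read_thermal <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF thermal rasters requires the tiff package", call. = FALSE)
    return(tiff::readTIFF(path, as.is = TRUE) * 1)
  }
  as.matrix(read.csv(path, header = FALSE, colClasses = "numeric"))
}
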