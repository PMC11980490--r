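# Build a channel_histogram directly from a 256-vector of counts (v = 0..255).
make_hist <- function(counts, channel = "G") {
  stopifnot(length(counts) == 256L)
  structure(list(counts = as.integer(counts), channel = channel),
            class = "channel_histogram")
}

# Discretised Gaussian histogram with total mass n (deterministic oracle).
gaussian_hist <- function(mean, sd, n = 1e6) {
  p <- diff(pnorm(seq(-0.5, 255.5, by = 1), mean, sd))
  make_hist(round(n * p / sum(p)))
}

# One full synthetic study, generated once per test run and shared.
.study_cache <- new.env(parent = emptyenv())

cached_study_dir <- function() {
  if (is.null(.study_cache$dir)) {
    .study_cache$dir <- file.path(tempdir(), "phytostress-shared-study")
    generate_study(.study_cache$dir, seed = 1)
  }
  .study_cache$dir
}

cached_study_report <- function() {
  if (is.null(.study_cache$report))
    .study_cache$report <- run_study(cached_study_dir())
  .study_cache$report
}
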