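two_peak_params <- function(noise_sd = 0, conc = 1, seed = 1) {
  dpv_gen_params(peaks = data.frame(position = c(-0.4, -0.9),
                                    height = c(10, 6),
                                    width = c(0.1, 0.1)),
                 baseline_slope = -2, concentration_scale = conc,
                 noise_sd = noise_sd, seed = seed)
}

test_that("baseline correction removes a pure line and is idempotent", {
  v <- seq(0, -1.5, by = -0.005)
  line <- voltammogram(v, -2 * v + 0.7)
  corrected <- baseline_correct(line)
  expect_lt(max(abs(corrected$current)), 1e-6)

  g <- generate_dpv(two_peak_params())
  once <- baseline_correct(g)
  twice <- baseline_correct(once)
  expect_lt(max(abs(twice$current - once$current)), 1e-6)

  # degenerate constant curve -> zero current
  expect_true(all(baseline_correct(voltammogram(v, rep(3, length(v))))$current == 0))
})

test_that("baseline correction preserves Gaussian peak heights within 2%", {
  g <- generate_dpv(two_peak_params())
  pk <- detect_peaks(baseline_correct(g))
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$height, c(10, 6), tolerance = 0.02)
})

test_that("peak detection recovers positions, widths and counts", {
  flat <- voltammogram(seq(0, -1.5, by = -0.005), rep(0, 301))
  expect_identical(nrow(detect_peaks(flat)), 0L)

  p3 <- dpv_gen_params(peaks = data.frame(position = c(-0.3, -0.75, -1.2),
                                          height = c(8, 12, 5),
                                          width = c(0.08, 0.1, 0.12)),
                       noise_sd = 0)
  pk <- detect_peaks(baseline_correct(generate_dpv(p3)))
  expect_identical(nrow(pk), 3L)
  expect_true(all(diff(pk$position) < 0))           # scan order, 0 -> -1.5 V
  expect_equal(pk$position, c(-0.3, -0.75, -1.2), tolerance = 0.005 / 0.3)
  expect_equal(pk$width, c(0.08, 0.1, 0.12), tolerance = 0.02)
})

test_that("detected heights are proportional to concentration (baseline removed)", {
  h1 <- detect_peaks(baseline_correct(generate_dpv(two_peak_params(conc = 1))))
  h2 <- detect_peaks(baseline_correct(generate_dpv(two_peak_params(conc = 2))))
  expect_identical(nrow(h2), nrow(h1))
  expect_equal(h2$height, 2 * h1$height, tolerance = 0.02)
})

test_that("clarity resolution follows the hand-computed pairwise formula", {
  mk <- function(pos, w) data.frame(position = pos, height = c(5, 5),
                                    width = w, prominence = c(5, 5))
  wide <- clarity(mk(c(-0.2, -0.7), c(0.1, 0.1)))
  expect_equal(wide$mean_resolution, 5.0)
  expect_false(wide$overlap_flag)

  tight <- clarity(mk(c(-0.5, -0.58), c(0.1, 0.1)))
  expect_equal(tight$mean_resolution, 0.8)
  expect_true(tight$overlap_flag)

  single <- clarity(data.frame(position = -0.5, height = 4, width = 0.1,
                               prominence = 4))
  expect_identical(single$n_peaks, 1L)
  expect_true(is.na(single$mean_resolution))
  expect_false(single$overlap_flag)
  expect_equal(single$total_peak_current, 4)
})

test_that("resolution is shift invariant and decreases as widths grow", {
  pk <- data.frame(position = c(-0.3, -0.7, -1.1), height = c(8, 9, 7),
                   width = c(0.1, 0.12, 0.11), prominence = c(8, 9, 7))
  shifted <- pk; shifted$position <- pk$position - 0.17
  expect_equal(clarity(shifted)$resolutions, clarity(pk)$resolutions)

  res <- sapply(c(1, 1.5, 2.5), function(k) {
    w <- pk; w$width <- pk$width * k
    clarity(w)$mean_resolution
  })
  expect_true(all(diff(res) < 0))
})

test_that("the default study contrast emerges: drought overlap, biochar concentration", {
  for (day in study_days()) {
    orig <- clarity(detect_peaks(baseline_correct(
      generate_dpv(default_dpv_params("original", day, seed = 60 + day)))))
    b4 <- clarity(detect_peaks(baseline_correct(
      generate_dpv(default_dpv_params("biochar4", day, seed = 80 + day)))))
    expect_identical(orig$overlap_flag, day >= 4)
    expect_false(b4$overlap_flag)
    expect_gt(b4$total_peak_current, orig$total_peak_current)
  }
})

test_that("invalid voltammograms and parameterisations are rejected", {
  expect_error(voltammogram(seq(0, -1.5, length.out = 5), rep(0, 5)), "10 samples")
  expect_error(voltammogram(c(0, -0.1, -0.1, seq(-0.2, -1, by = -0.1)),
                            rep(0, 12)), "decreasing")
  expect_error(dpv_gen_params(v_start = -1.5, v_end = 0), "negative-going")
  expect_error(dpv_gen_params(peaks = data.frame(position = 0.5, height = 1,
                                                 width = 0.1)), "inside")
  expect_error(dpv_gen_params(peaks = data.frame(position = -0.5, height = 0,
                                                 width = 0.1)), "height")
})

test_that("an empty peak set with no noise yields a straight line and zero peaks", {
  v <- generate_dpv(dpv_gen_params(noise_sd = 0))
  fit <- lm(v$current ~ v$potential)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_identical(nrow(detect_peaks(baseline_correct(v))), 0L)
})
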