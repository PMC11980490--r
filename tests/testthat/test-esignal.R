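test_that("a pure noiseless carrier has an exact peak-to-peak amplitude", {
  p <- esignal_gen_params(fs = 2000, duration = 2, carrier_freq = 50,
                          carrier_pp = 2, slow_freq = 0.5,
                          slow_amp_fraction = 0, noise_sd = 0)
  s <- generate_esignal(p)
  expect_identical(length(s$samples), 4000L)
  st <- signal_stats(s)
  expect_equal(st$peak_v, 2.0)
  expect_equal(st$period_ms, 20.0, tolerance = 1e-3)
})

test_that("noise inflates the measured peak-to-peak only slightly", {
  p <- default_esignal_params("original", 6, seed = 1)  # carrier_pp 5.008
  st <- signal_stats(generate_esignal(p))
  expect_gte(st$peak_v, 5.008)
  expect_lte(st$peak_v, 5.008 * 1.03)
})

test_that("peak-to-peak reproduces the published extremes and scales linearly", {
  ref <- esignal_reference()
  row <- ref[ref$treatment == "original" & ref$day == 6, ]
  s <- phyto_signal(c(row$max_v, 0.1, row$min_v, 0), fs = 10)
  expect_equal(signal_stats(s)$peak_v, 5.008)

  k <- 3.7
  base <- generate_esignal(esignal_gen_params(duration = 5, slow_freq = 0.4,
                                              seed = 2))
  a <- signal_stats(base); b <- signal_stats(phyto_signal(k * base$samples, base$fs))
  expect_equal(b$peak_v, k * a$peak_v)
  expect_equal(b$max_v, k * a$max_v)
  expect_equal(b$period_ms, a$period_ms)
})

test_that("constant signals have zero peak-to-peak and an undefined period", {
  st <- signal_stats(phyto_signal(rep(1.5, 100), fs = 100))
  expect_equal(st$peak_v, 0)
  expect_true(is.na(st$period_ms))
})

test_that("the autocorrelation period is exact on noiseless sines from 10 to 100 Hz", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  for (f in c(10, 20, 25, 40, 50, 80, 100)) {
    per <- estimate_period(phyto_signal(sin(2 * pi * f * t), fs))
    expect_equal(per, 1000 / f, tolerance = 0.5 / (1000 / f))  # one lag = 0.5 ms
  }
})

test_that("white noise has no qualifying autocorrelation peak", {
  x <- withr::with_seed(99, rnorm(8000))
  expect_true(is.na(estimate_period(phyto_signal(x, 2000))))
})

test_that("the amplitude spectrum reads sinusoid amplitudes directly", {
  fs <- 1000; n <- 1000
  t <- (0:(n - 1)) / fs
  s <- phyto_signal(1.0 * sin(2 * pi * 50 * t), fs)
  sp <- amplitude_spectrum(s)
  expect_equal(sp$amps[which(sp$freqs == 50)], 1.0, tolerance = 1e-9)
  # two-tone: two spectral lines at the generated frequencies
  s2 <- phyto_signal(0.8 * sin(2 * pi * 50 * t) + 0.3 * cos(2 * pi * 120 * t), fs)
  sp2 <- amplitude_spectrum(s2)
  expect_equal(sp2$amps[which(sp2$freqs == 50)], 0.8, tolerance = 1e-9)
  expect_equal(sp2$amps[which(sp2$freqs == 120)], 0.3, tolerance = 1e-9)
  expect_lt(sort(sp2$amps, decreasing = TRUE)[3], 1e-9)
  expect_true(all(diff(sp2$freqs) > 0))
})

test_that("the one-sided spectrum satisfies Parseval's identity", {
  x <- withr::with_seed(7, rnorm(4096))
  s <- phyto_signal(x, 2000)
  sp <- amplitude_spectrum(s, detrend = FALSE)
  n <- length(x)
  half <- n %/% 2 + 1
  # undo the one-sided doubling: energy = A_DC^2 + sum(A_k^2/2) + A_Nyq^2
  energy <- sp$amps[1]^2 + sum(sp$amps[2:(half - 1)]^2) / 2 + sp$amps[half]^2
  expect_equal(energy, mean(x^2), tolerance = 1e-6)
})

test_that("the characteristic sub-5 Hz frequency is recovered at 0.37 Hz", {
  s <- generate_esignal(default_esignal_params("original", 6, seed = 1))
  cp <- characteristic_frequency(amplitude_spectrum(s))
  expect_equal(cp$freq, 0.37)
  # slow-wave amplitude read directly: carrier_pp/2 * slow_amp_fraction
  expect_equal(cp$amp, 5.008 / 2 * 0.20, tolerance = 0.01)

  # empty band
  flat <- structure(list(freqs = seq(0, 10, by = 0.5),
                         amps = c(1, rep(0, 10), rep(1, 10))),
                    class = "amplitude_spectrum")
  expect_true(is.na(characteristic_frequency(flat, band_max = 5)$freq))
})

test_that("characteristic-frequency recovery holds across seeds and grows with drought", {
  hits <- sapply(1:20, function(sd) {
    s <- generate_esignal(default_esignal_params("biochar2", 2, seed = sd))
    characteristic_frequency(amplitude_spectrum(s))$freq
  })
  expect_gte(mean(hits == 0.37), 0.95)

  for (tr in study_treatments()) {
    amp0 <- characteristic_frequency(amplitude_spectrum(
      generate_esignal(default_esignal_params(tr, 0, seed = 1))))$amp
    amp6 <- characteristic_frequency(amplitude_spectrum(
      generate_esignal(default_esignal_params(tr, 6, seed = 2))))$amp
    expect_gt(amp6, amp0)
  }
})

test_that("invalid signal parameterisations are rejected", {
  expect_error(esignal_gen_params(fs = 80, carrier_freq = 50), "twice")
  expect_error(esignal_gen_params(slow_freq = 6), "slow_freq")
  expect_error(esignal_gen_params(duration = 10, slow_freq = 0.37), "integer")
  expect_error(esignal_gen_params(slow_amp_fraction = 1), "slow_amp_fraction")
  expect_error(phyto_signal(c(1, NA), 10), "finite")
})
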