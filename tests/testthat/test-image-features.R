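test_that("channel histograms count masked pixels and conserve totals", {
  img <- array(0L, dim = c(2, 3, 3))
  img[, , 2] <- matrix(c(10L, 10L, 20L, 30L, 40L, 50L), nrow = 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), nrow = 2)
  h <- channel_histogram(img, mask, "G")
  expect_identical(h$counts[10 + 1], 2L)
  expect_identical(h$counts[20 + 1], 1L)
  expect_identical(sum(h$counts), sum(mask))

  h0 <- channel_histogram(img, mask & FALSE, "G")
  expect_true(all(h0$counts == 0L))

  # conservation on a generated image, every channel
  p <- image_gen_params(width = 80, height = 60, n_foreground = 900,
                        channel_means = c(120, 150, 90),
                        channel_sds = c(25, 25, 25), seed = 2)
  gi <- generate_plant_image(p)
  for (ch in c("R", "G", "B"))
    expect_identical(sum(channel_histogram(gi, gi$mask, ch)$counts), 900L)
})

test_that("integral area excludes the zero bin", {
  c1 <- rep(0L, 256); c1[10 + 1] <- 2L; c1[20 + 1] <- 1L
  expect_identical(integral_area(make_hist(c1)), 3L)
  c2 <- rep(0L, 256); c2[0 + 1] <- 5L; c2[50 + 1] <- 7L
  expect_identical(integral_area(make_hist(c2)), 7L)
  expect_identical(integral_area(make_hist(rep(0L, 256))), 0L)
})

test_that("barycenter is the zero-excluded intensity-weighted mean", {
  c1 <- rep(0L, 256); c1[100 + 1] <- 1234L
  expect_equal(barycenter(make_hist(c1)), 100)
  c2 <- rep(0L, 256); c2[50 + 1] <- 1L; c2[150 + 1] <- 3L
  expect_equal(barycenter(make_hist(c2)), 125)
  # zero-bin mass is ignored
  c2[0 + 1] <- 1000L
  expect_equal(barycenter(make_hist(c2)), 125)
  expect_error(barycenter(make_hist(rep(0L, 256))), "empty")
})

test_that("fwhm follows the interpolated half-maximum convention", {
  spike <- rep(0L, 256); spike[80 + 1] <- 1000L
  expect_equal(fwhm(make_hist(spike), smooth_window = 1), 1.0)

  # symmetric triangle over [90, 110], peak at 100: crossings at 95 and 105
  tri <- rep(0L, 256)
  tri[(90:110) + 1] <- c(0:10, 9:0) * 10L
  expect_equal(fwhm(make_hist(tri), smooth_window = 1), 10.0)

  # discretised Gaussian: FWHM = 2.3548 sd within 3% (default smoothing)
  expect_equal(fwhm(gaussian_hist(120, 10)), 2.3548 * 10, tolerance = 0.03)

  # peak against the upper boundary: one-sided width doubled and flagged
  half <- rep(0L, 256)
  half[156:256] <- round(1e5 * dnorm(100:0, 0, 15))
  w <- fwhm(make_hist(half), smooth_window = 1)
  expect_true(isTRUE(attr(w, "one_sided")))
  expect_equal(as.numeric(w), 2 * 2.3548 * 15 / 2, tolerance = 0.05)

  expect_error(fwhm(make_hist(rep(0L, 256))), "empty")
})

test_that("barycenter and fwhm are scale invariant; barycenter is shift covariant", {
  h <- gaussian_hist(130, 12, n = 2e5)
  h3 <- make_hist(h$counts * 3L)
  expect_equal(barycenter(h3), barycenter(h))
  expect_equal(as.numeric(fwhm(h3)), as.numeric(fwhm(h)))

  for (delta in c(5L, 17L)) {
    shifted <- make_hist(c(rep(0L, delta), h$counts[1:(256 - delta)]))
    expect_equal(barycenter(shifted), barycenter(h) + delta, tolerance = 1e-10)
  }
})

test_that("green dominance matches the published drought benchmarks and its invariants", {
  expect_equal(round(100 * green_dominance(122.18904, 155.77954, 94.29842), 1), 41.8)
  expect_equal(round(100 * green_dominance(161.17829, 183.06305, 119.85221), 1), 39.4)
  expect_equal(green_dominance(80, 80, 80), 1 / 3)
  expect_error(green_dominance(0, 10, 10), "positive")
  expect_error(green_dominance(10, -1, 10), "positive")
  # in (0,1) and strictly increasing in the green barycenter
  g <- seq(10, 250, by = 40)
  gd <- sapply(g, function(gb) green_dominance(120, gb, 95))
  expect_true(all(gd > 0 & gd < 1))
  expect_true(all(diff(gd) > 0))
})

test_that("segmentation recovers the synthetic plant and drops specks", {
  img <- array(50L, dim = c(20, 30, 3))
  expect_false(any(segment_plant(img, bg_level = 50, tol = 10)))

  # tol = 0: every differing pixel selected before the area filter
  img[3, 4, 1] <- 51L
  expect_identical(sum(segment_plant(img, bg_level = 50, tol = 0,
                                     min_component = 1L)), 1L)
  # ... and removed by the small-component filter
  expect_false(any(segment_plant(img, bg_level = 50, tol = 0)))

  p <- default_image_params("original", 0, scale_down = 10, seed = 5)
  gi <- generate_plant_image(p)
  m <- segment_plant(gi)
  jaccard <- sum(m & gi$mask) / sum(m | gi$mask)
  expect_gte(jaccard, 0.99)
})

test_that("image_feature_row composes features and flags undefined cells", {
  p <- image_gen_params(width = 100, height = 80, n_foreground = 3000,
                        channel_means = c(120, 160, 100),
                        channel_sds = c(8, 8, 8), seed = 9)
  gi <- generate_plant_image(p)
  row <- image_feature_row(gi)
  expect_true(row$defined)
  # no channel can reach 0 at these means/sds: areas equal across channels
  expect_identical(c(row$r_area, row$g_area, row$b_area), rep(3000L, 3))
  expect_equal(row$gd,
               green_dominance(row$r_bary, row$g_bary, row$b_bary))

  empty <- image_feature_row(gi$image, gi$mask & FALSE)
  expect_false(empty$defined)
  expect_true(all(is.na(empty[, c("r_bary", "g_fwhm", "gd")])))
})
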