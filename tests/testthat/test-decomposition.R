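test_that("background estimation recovers known flat backgrounds", {
  s <- quick_settings(total_counts = 2e5, background_fraction = 0.10)
  sp <- simulate_spectrum(s, mean_row_truth(seed = 3L))
  bg_true <- 0.10 * s$total_counts / s$n_channels  # ~19.5 counts/channel
  est <- estimate_background(sp)
  expect_lt(abs(est - bg_true), 4 * sqrt(bg_true))

  # zero-background simulation: estimate consistent with zero
  sp0 <- simulate_spectrum(quick_settings(), mean_row_truth(seed = 4L))
  expect_lte(estimate_background(sp0), 1)

  expect_identical(estimate_background(data.frame(counts = integer(100))), 0)
})

test_that("three-component fit recovers simulation truth", {
  s <- quick_settings(total_counts = 5e5, n_channels = 2048L)
  sp <- simulate_spectrum(s, mean_row_truth(seed = 17L))
  f <- fit_components(sp)
  expect_true(f$converged)
  expect_equal(f$lifetimes[3], 1.83, tolerance = 0.02)
  expect_equal(f$intensities[3], 9.01, tolerance = 0.10 * 9.01)
  # structural invariants of every returned fit
  expect_true(all(diff(f$lifetimes) > 0))
  expect_equal(sum(f$intensities), 100, tolerance = 1e-6)
  expect_gt(f$chi2_red, 0)
})

test_that("noiseless input is recovered to high accuracy", {
  # high statistics so that integer rounding of the model curve (which
  # systematically truncates the sub-0.5-count tail) stays negligible
  s <- quick_settings(total_counts = 1e8, n_channels = 2048L)
  tr <- mean_row_truth()
  es <- expected_spectrum(s, tr)
  sp <- tibble::tibble(channel = es$channel, counts = round(es$expected))
  f <- fit_components(sp, settings = s)
  expect_equal(f$lifetimes, tr$lifetimes, tolerance = 0.005)
  expect_equal(f$intensities, 100 * tr$intensities, tolerance = 0.005)
})

test_that("single-component fit normalizes to exactly 100 percent", {
  s <- quick_settings(total_counts = 1e5)
  sp <- simulate_spectrum(s, ground_truth(1.8, 1, seed = 5L))
  f <- fit_components(sp, n_components = 1)
  expect_identical(f$intensities, 100)
  expect_equal(f$lifetimes, 1.8, tolerance = 0.05)
})

test_that("fit guards reject bad component counts and starved spectra", {
  s <- quick_settings()
  sp <- simulate_spectrum(s, mean_row_truth(seed = 6L))
  expect_error(fit_components(sp, n_components = 0), "between 1 and 4")
  expect_error(fit_components(sp, n_components = 5), "between 1 and 4")
  tiny <- simulate_spectrum(quick_settings(total_counts = 5e3),
                            mean_row_truth(seed = 7L))
  expect_error(fit_components(tiny), "1e4 counts")
  expect_error(fit_components(tibble::tibble(counts = rpois(100, 50))),
               "settings")
})

test_that("mean lifetime is the intensity-weighted component average", {
  one <- data.frame(lifetime_ns = 2.0, intensity_pct = 100)
  expect_equal(mean_lifetime(one), 2.0)
  three <- data.frame(lifetime_ns = c(0.125, 0.40, 1.83),
                      intensity_pct = c(25, 66, 9))
  expect_equal(mean_lifetime(three), 0.03125 + 0.264 + 0.1647,
               tolerance = 1e-12)  # hand sum, prints as 0.460
  expect_equal(mean_lifetime(three[c(3, 1, 2), ]), mean_lifetime(three))
})

test_that("tidy and glance expose the fitted decomposition", {
  s <- quick_settings(total_counts = 1e5)
  sp <- simulate_spectrum(s, mean_row_truth(seed = 8L))
  f <- fit_components(sp)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("component", "lifetime_ns", "lifetime_se",
                     "intensity_pct", "intensity_se"))
  expect_equal(nrow(td), 3)
  expect_true(all(td$lifetime_se > 0, na.rm = TRUE))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$tau_mean_ns, mean_lifetime(f))
  expect_true(gl$converged)
})
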