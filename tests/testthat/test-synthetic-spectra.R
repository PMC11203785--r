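test_that("constructors reject invalid acquisition and truth parameters", {
  expect_error(acquisition(channel_width = 0))
  expect_error(acquisition(t0_channel = 9000), "t0_channel")
  expect_error(acquisition(background_fraction = 1), "background_fraction")
  expect_error(ground_truth(c(0.4, 0.4), c(0.5, 0.5)), "increasing")
  expect_error(ground_truth(c(0.1, 0.4), c(0.6, 0.3)), "sum to 1")
  expect_error(ground_truth(c(0.1, 0.4), c(-0.1, 1.1)), "positive")
  expect_error(ground_truth(0.4, 1, source_term = c(0.382, 0.5)), "0.25")
})

test_that("truth_from_row applies the 1:3 p-Ps/o-Ps split and its guards", {
  tr <- truth_from_row(1.83, 9.01)
  expect_equal(tr$lifetimes, c(0.125, 0.40, 1.83))
  expect_equal(tr$intensities, c(0.0901 / 3, 1 - 0.0901 / 3 - 0.0901, 0.0901),
               tolerance = 1e-12)
  expect_equal(truth_from_row(1.86, 8.96)$intensities[3], 0.0896)
  expect_error(truth_from_row(1.83, 75), "75")
  # no positronium formed: only the free-positron component survives
  tr0 <- truth_from_row(1.83, 0)
  expect_equal(tr0$lifetimes, 0.40)
  expect_equal(tr0$intensities, 1)
})

test_that("expected spectrum follows pure exponential decay without IRF", {
  s <- quick_settings(irf_fwhm = 0, n_channels = 2048L)
  tr <- ground_truth(1.83, 1)
  es <- expected_spectrum(s, tr)
  # ratio of channel contents separated by dt is exp(-dt/tau): the channel
  # integral and the window renormalization cancel exactly
  i1 <- 400L; dch <- 50L
  dt <- dch * s$channel_width / 1000
  ratio <- es$expected[i1 + dch] / es$expected[i1]
  expect_equal(ratio, exp(-dt / 1.83), tolerance = 1e-10)
})

test_that("expected spectrum is non-negative and sums to total_counts", {
  s <- quick_settings()
  truths <- list(
    mean_row_truth(),
    ground_truth(c(0.125, 0.40, 5.0), c(0.03, 0.88, 0.09)),
    ground_truth(c(0.125, 0.40, 1.83), c(0.03, 0.88, 0.09),
                 source_term = c(0.382, 0.10))
  )
  settings <- list(s, quick_settings(background_fraction = 0.05))
  for (tr in truths) {
    for (st in settings) {
      es <- expected_spectrum(st, tr)
      expect_true(all(es$expected >= 0))
      expect_equal(sum(es$expected), st$total_counts,
                   tolerance = 1e-3)  # normalization invariant, 0.1%
    }
  }
})

test_that("spectrum tail decays with the o-Ps lifetime", {
  s <- acquisition(total_counts = 1e6)
  tr <- ground_truth(c(0.125, 0.40, 1.83), c(0.0300, 0.8799, 0.0901))
  es <- expected_spectrum(s, tr)
  win <- es$time_ns > 5 & es$time_ns < 15
  fit <- lm(log(expected) ~ time_ns, data = es[win, ])
  tau_tail <- -1 / coef(fit)[[2]]
  expect_equal(tau_tail, 1.83, tolerance = 0.01)
})

test_that("expected counts decrease monotonically past the IRF region", {
  s <- quick_settings()
  es <- expected_spectrum(s, mean_row_truth())
  sigma_ch <- s$irf_fwhm / (2 * sqrt(2 * log(2))) / s$channel_width
  past <- es$channel > s$t0_channel + ceiling(3 * sigma_ch)
  expect_true(all(diff(es$expected[past]) < 0))
})

test_that("unresolvably short lifetimes are rejected", {
  s <- quick_settings()  # 26 ps channels
  expect_error(expected_spectrum(s, ground_truth(0.0009, 1)), "resolved")
})

test_that("simulation is a pure function of settings, truth and seed", {
  s <- quick_settings()
  tr <- mean_row_truth(seed = 99L)
  sp1 <- simulate_spectrum(s, tr)
  sp2 <- simulate_spectrum(s, tr)
  expect_identical(sp1$counts, sp2$counts)
  sp3 <- simulate_spectrum(s, tr, seed = 100L)
  expect_false(identical(sp1$counts, sp3$counts))
})

test_that("realized totals fluctuate within Poisson range of total_counts", {
  s <- acquisition(total_counts = 1e6, n_channels = 2048L,
                   channel_width = 26, t0_channel = 300)
  for (seed in 1:3) {
    sp <- simulate_spectrum(s, mean_row_truth(seed = seed))
    expect_lt(abs(sum(sp$counts) - 1e6), 4 * sqrt(1e6))
  }
})

test_that("channel-wise variance matches channel-wise mean (Poisson)", {
  s <- quick_settings(total_counts = 2e4, n_channels = 256L,
                      channel_width = 100, t0_channel = 40)
  tr <- mean_row_truth()
  sims <- vapply(1:200, function(i) {
    simulate_spectrum(s, tr, seed = 5000L + i)$counts
  }, numeric(s$n_channels))
  m <- rowMeans(sims)
  v <- apply(sims, 1, var)
  keep <- m >= 5
  ratio <- mean(v[keep] / m[keep])
  # 200 replicates: var/mean has sd sqrt(2/199) per channel, ~0.01 averaged
  expect_gt(ratio, 0.93)
  expect_lt(ratio, 1.07)
})
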