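# Small, fast acquisition geometries used across the suite. The full-size
# default geometry (8192 x 6.5 ps, 1e6 counts) is exercised in the
# acceptance tests; unit tests use coarser channels so each simulated
# spectrum and fit stays in the sub-second range.

quick_settings <- function(total_counts = 1e5, n_channels = 1024L,
                           channel_width = 26, t0_channel = 200,
                           irf_fwhm = 250, background_fraction = 0) {
  acquisition(
    channel_width = channel_width, n_channels = n_channels,
    total_counts = total_counts, t0_channel = t0_channel,
    irf_fwhm = irf_fwhm, background_fraction = background_fraction
  )
}

mean_row_truth <- function(seed = 1L) truth_from_row(1.83, 9.01, seed = seed)

# Independent dense-grid inverse of the confinement relation: tabulate the
# forward map on a fine radius grid and interpolate tau -> R. Never calls
# the package's root-finding inverse.
grid_inverse_oracle <- function(tau3, delta_R = 0.1656, n_grid = 400000L) {
  R <- seq(1e-4, 1, length.out = n_grid)
  x <- R / (R + delta_R)
  tau <- 0.5 / (1 - x + sin(2 * pi * x) / (2 * pi))
  stats::approx(tau, R, xout = tau3)$y
}
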