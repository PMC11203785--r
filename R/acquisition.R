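#' Acquisition settings for a lifetime histogram
#'
#' Describes the multichannel-analyzer geometry and counting statistics of a
#' PALS measurement: channel width, number of channels, total counts under the
#' curve, the channel position of the time-zero centroid, the Gaussian
#' instrument-response FWHM, and the fraction of counts in a flat random
#' background. Defaults mirror a conventional fast-fast coincidence
#' spectrometer: 6.5 ps channels, 8192 channels, 1e6 counts.
#'
#' @param channel_width Channel width in picoseconds (> 0).
#' @param n_channels Number of channels (>= 2).
#' @param total_counts Expected total counts under the spectrum (> 0).
#' @param t0_channel Real-valued channel position of the time-zero centroid,
#'   in `[0, n_channels)`. The default 1000 leaves a pre-peak region used for
#'   background estimation.
#' @param irf_fwhm Full width at half maximum of the Gaussian instrument
#'   response, in picoseconds (>= 0; 0 disables timing broadening).
#' @param background_fraction Fraction of `total_counts` distributed uniformly
#'   over all channels, in `[0, 1)`.
#'
#' @return An object of class `pals_acquisition` (a named list).
#' @examples
#' acquisition()
#' acquisition(total_counts = 1e5, irf_fwhm = 0)
#' @export
acquisition <- function(channel_width = 6.5,
                        n_channels = 8192L,
                        total_counts = 1e6,
                        t0_channel = 1000,
                        irf_fwhm = 250,
                        background_fraction = 0) {
  stopifnot(
    is.numeric(channel_width), length(channel_width) == 1L, channel_width > 0,
    is.numeric(n_channels), length(n_channels) == 1L, n_channels >= 2,
    is.numeric(total_counts), length(total_counts) == 1L, total_counts > 0,
    is.numeric(t0_channel), length(t0_channel) == 1L,
    is.numeric(irf_fwhm), length(irf_fwhm) == 1L, irf_fwhm >= 0,
    is.numeric(background_fraction), length(background_fraction) == 1L
  )
  if (t0_channel < 0 || t0_channel >= n_channels) {
    abort("`t0_channel` must lie in [0, n_channels).")
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    abort("`background_fraction` must lie in [0, 1).")
  }
  structure(
    list(
      channel_width = channel_width,
      n_channels = as.integer(n_channels),
      total_counts = total_counts,
      t0_channel = t0_channel,
      irf_fwhm = irf_fwhm,
      background_fraction = background_fraction
    ),
    class = "pals_acquisition"
  )
}

#' @export
print.pals_acquisition <- function(x, ...) {
  cat("<pals_acquisition>\n")
  cat(sprintf("  channels: %d x %.3g ps (window %.1f ns)\n",
              x$n_channels, x$channel_width,
              x$n_channels * x$channel_width / 1000))
  cat(sprintf("  t0 channel: %.1f; IRF FWHM: %.0f ps\n",
              x$t0_channel, x$irf_fwhm))
  cat(sprintf("  total counts: %.3g; background fraction: %.3g\n",
              x$total_counts, x$background_fraction))
  invisible(x)
}

#' Ground-truth decay parameters for spectrum simulation
#'
#' Bundles the true lifetimes and relative intensities of the annihilation
#' components (ordinarily p-Ps, free positron, o-Ps), plus an optional source
#' term for annihilation in the Kapton foil wrapping the positron source, and
#' a seed. Intensities are fractions of the signal (excluding background) and
#' must sum to one.
#'
#' @param lifetimes Strictly increasing component lifetimes in ns.
#' @param intensities Positive fractions summing to 1 (tolerance 1e-12).
#' @param source_term Optional `c(lifetime_ns, intensity_fraction)` for a
#'   source (foil) component; the intensity is the fraction of total signal
#'   counts attributed to the source, in `[0, 0.25]`.
#' @param seed Integer seed recorded with simulated spectra.
#'
#' @return An object of class `pals_truth`.
#' @examples
#' ground_truth(c(0.125, 0.40, 1.83), c(0.0300, 0.8799, 0.0901))
#' @export
ground_truth <- function(lifetimes, intensities, source_term = NULL,
                         seed = 1L) {
  stopifnot(is.numeric(lifetimes), is.numeric(intensities),
            length(lifetimes) == length(intensities),
            length(lifetimes) >= 1L)
  if (any(diff(lifetimes) <= 0)) {
    abort("Component lifetimes must be strictly increasing.")
  }
  if (any(intensities <= 0)) {
    abort("Component intensities must all be positive.")
  }
  if (abs(sum(intensities) - 1) > 1e-12) {
    abort("Component intensities must sum to 1 (within 1e-12).")
  }
  if (!is.null(source_term)) {
    stopifnot(is.numeric(source_term), length(source_term) == 2L)
    if (source_term[1] <= 0) abort("Source lifetime must be positive.")
    if (source_term[2] < 0 || source_term[2] > 0.25) {
      abort("Source intensity must be a fraction in [0, 0.25].")
    }
  }
  structure(
    list(
      lifetimes = as.numeric(lifetimes),
      intensities = as.numeric(intensities),
      source_term = source_term,
      seed = as.integer(seed)
    ),
    class = "pals_truth"
  )
}

#' @export
print.pals_truth <- function(x, ...) {
  cat("<pals_truth>\n")
  for (i in seq_along(x$lifetimes)) {
    cat(sprintf("  component %d: tau = %.4g ns, I = %.4g%%\n",
                i, x$lifetimes[i], 100 * x$intensities[i]))
  }
  if (!is.null(x$source_term)) {
    cat(sprintf("  source term: tau = %.4g ns, I = %.4g%%\n",
                x$source_term[1], 100 * x$source_term[2]))
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Build a three-component ground truth from an o-Ps summary row
#'
#' Expands a measured (tau3, I3) pair into a full three-component truth using
#' the positronium spin statistics: one quarter of the positronium yield forms
#' p-Ps and three quarters o-Ps, so I1 = I3 / 3. The p-Ps lifetime defaults to
#' the 0.125 ns vacuum value and the free-positron lifetime to 0.40 ns; the
#' free-positron intensity takes up the remainder.
#'
#' @param tau3 o-Ps lifetime in ns.
#' @param I3 o-Ps intensity in percent. Values >= 75 are rejected (they would
#'   force a negative free-positron intensity).
#' @param tau1,tau2 p-Ps and free-positron lifetimes in ns.
#' @param seed Seed stored in the returned truth.
#'
#' @return A `pals_truth` with components (p-Ps, free positron, o-Ps). When
#'   `I3 = 0` the positronium channels vanish and a single-component truth
#'   (free positron only) is returned.
#' @examples
#' truth_from_row(tau3 = 1.83, I3 = 9.01)
#' @export
truth_from_row <- function(tau3, I3, tau1 = 0.125, tau2 = 0.40, seed = 1L) {
  stopifnot(is.numeric(tau3), length(tau3) == 1L, tau3 > 0,
            is.numeric(I3), length(I3) == 1L, I3 >= 0)
  if (I3 >= 75) {
    abort("I3 >= 75% leaves no intensity for the free-positron component.")
  }
  f3 <- I3 / 100
  f1 <- f3 / 3          # p-Ps : o-Ps = 1 : 3
  f2 <- 1 - f1 - f3
  if (f3 == 0) {
    return(ground_truth(tau2, 1, seed = seed))
  }
  ground_truth(c(tau1, tau2, tau3), c(f1, f2, f3), seed = seed)
}
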