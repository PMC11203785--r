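# Closed-form channel contents of an exponential decay convolved with a
# Gaussian instrument response (exponentially modified Gaussian, EMG).
# Channel i (0-based) spans times [(i - 0.5 - t0) * w, (i + 0.5 - t0) * w]
# relative to the time-zero centroid, so channel centers sit at
# t = (i - t0_channel) * channel_width.

# CDF of the EMG at times t (ns) relative to t0 = 0, decay lifetime tau (ns),
# Gaussian sd sigma (ns). Evaluated on the log scale where the cancellation
# between the exploding exponential and the vanishing normal tail is severe.
emg_cdf <- function(t, tau, sigma) {
  if (sigma <= 0) {
    out <- 1 - exp(-pmax(t, 0) / tau)
    out[t <= 0] <- 0
    return(out)
  }
  u <- t / sigma
  lam <- 1 / tau
  pnorm(u) - exp(-lam * t + 0.5 * (lam * sigma)^2 +
                   pnorm(u - lam * sigma, log.p = TRUE))
}

# Per-channel probabilities of one decay component, renormalized over the
# finite acquisition window so long lifetimes still integrate to one.
component_channel_probs <- function(tau, settings) {
  w <- settings$channel_width / 1000  # ns
  sigma <- settings$irf_fwhm / 1000 / (2 * sqrt(2 * log(2)))
  edges <- (seq(0L, settings$n_channels) - 0.5 - settings$t0_channel) * w
  cdf <- emg_cdf(edges, tau, sigma)
  p <- diff(cdf)
  total <- cdf[length(cdf)] - cdf[1L]
  if (total <= 0) abort("Decay component lies entirely outside the window.")
  pmax(p / total, 0)
}

#' Noiseless expected spectrum for a ground truth
#'
#' Evaluates the analytic model underlying both the simulator and the fitting
#' stage: each decay component is an exponential starting at the time-zero
#' centroid, convolved with the Gaussian instrument response and integrated
#' over each channel in closed form; a flat background and an optional source
#' (foil) component are added; every component is renormalized over the
#' acquisition window so the channel sum equals `total_counts` exactly.
#'
#' @param settings A [acquisition()] object.
#' @param truth A [ground_truth()] object.
#'
#' @return A tibble with columns `channel` (0-based), `time_ns` (channel
#'   center relative to t0) and `expected` (expected counts).
#' @examples
#' s <- acquisition(n_channels = 2048, total_counts = 1e5)
#' tr <- truth_from_row(1.83, 9.01)
#' sp <- expected_spectrum(s, tr)
#' sum(sp$expected)
#' @export
expected_spectrum <- function(settings, truth) {
  stopifnot(inherits(settings, "pals_acquisition"),
            inherits(truth, "pals_truth"))
  w_ns <- settings$channel_width / 1000
  taus <- truth$lifetimes
  fracs <- truth$intensities
  if (!is.null(truth$source_term)) {
    fs <- truth$source_term[2]
    taus <- c(taus, truth$source_term[1])
    fracs <- c(fracs * (1 - fs), fs)
  }
  if (any(taus < w_ns / 10)) {
    abort("A component lifetime is shorter than one tenth of a channel width and cannot be resolved.")
  }
  signal <- rowSums(vapply(
    seq_along(taus),
    function(i) fracs[i] * component_channel_probs(taus[i], settings),
    numeric(settings$n_channels)
  ))
  b <- settings$background_fraction
  expected <- settings$total_counts *
    ((1 - b) * signal + b / settings$n_channels)
  tibble::tibble(
    channel = seq_len(settings$n_channels) - 1L,
    time_ns = (seq_len(settings$n_channels) - 1L - settings$t0_channel) * w_ns,
    expected = expected
  )
}

#' Simulate a lifetime spectrum with Poisson counting noise
#'
#' Draws each channel's count from a Poisson law whose mean is the
#' [expected_spectrum()] model, reproducibly under the truth's seed (or an
#' explicit override). The result is a Monte-Carlo twin of a measured
#' channel histogram.
#'
#' @inheritParams expected_spectrum
#' @param seed Optional integer overriding `truth$seed`.
#'
#' @return A `pals_spectrum`: a tibble with columns `channel`, `time_ns` and
#'   `counts`, carrying the settings and seed as attributes.
#' @examples
#' s <- acquisition(n_channels = 1024, total_counts = 1e5)
#' sp <- simulate_spectrum(s, truth_from_row(1.83, 9.01, seed = 42))
#' sum(sp$counts)
#' @export
simulate_spectrum <- function(settings, truth, seed = NULL) {
  model <- expected_spectrum(settings, truth)
  seed <- as.integer(seed %||% truth$seed)
  counts <- withr::with_seed(seed, rpois(nrow(model), model$expected))
  out <- tibble::tibble(
    channel = model$channel,
    time_ns = model$time_ns,
    counts = as.integer(counts)
  )
  new_pals_spectrum(out, settings, seed)
}

new_pals_spectrum <- function(data, settings, seed = NA_integer_) {
  structure(
    data,
    settings = settings,
    seed = seed,
    class = c("pals_spectrum", class(tibble::tibble()))
  )
}

#' @export
print.pals_spectrum <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("<pals_spectrum> %d channels x %.3g ps, %d counts, seed %s\n",
              nrow(x), s$channel_width, sum(x$counts),
              format(attr(x, "seed"))))
  NextMethod()
}
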