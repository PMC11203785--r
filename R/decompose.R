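#' Estimate the flat background of a lifetime spectrum
#'
#' Uses the median of the pre-peak region (channels well before the time-zero
#' peak) when at least 50 such channels exist, otherwise the median of the
#' final 5% of channels. Medians are used because both regions still carry
#' Poisson noise and, in the tail case, a decaying remnant of the slowest
#' component.
#'
#' @param spectrum A `pals_spectrum` or a data frame with a `counts` column.
#' @param peak_margin Channels excluded below the peak to keep the rising
#'   edge of the instrument response out of the pre-peak region.
#'
#' @return Background level in counts/channel (non-negative scalar).
#' @export
estimate_background <- function(spectrum, peak_margin = 100L) {
  counts <- spectrum$counts
  if (is.null(counts)) abort("`spectrum` must have a `counts` column.")
  n <- length(counts)
  if (all(counts == 0)) return(0)
  peak <- which.max(counts)
  pre_end <- peak - peak_margin
  if (pre_end >= 50L) {
    return(max(0, median(counts[seq_len(pre_end)])))
  }
  n_tail <- max(1L, floor(0.05 * n))
  if (n_tail < 200L && n - n_tail < 1L) {
    abort("Spectrum has neither a usable pre-peak region nor a tail region.")
  }
  max(0, median(counts[(n - n_tail + 1L):n]))
}

# Model used by the fitter: free amplitudes per component (total counts in
# each), plus t0, IRF FWHM and flat background. An optional source component
# has its lifetime fixed and its amplitude tied to the stated fraction of the
# signal.
fit_model_counts <- function(par, n_comp, settings0, source = NULL) {
  taus <- exp(par[seq_len(n_comp)])
  amps <- par[n_comp + seq_len(n_comp)]
  t0 <- par[2 * n_comp + 1L]
  fwhm <- par[2 * n_comp + 2L]
  bg <- par[2 * n_comp + 3L]
  s <- settings0
  s$t0_channel <- t0
  s$irf_fwhm <- fwhm
  sig <- numeric(s$n_channels)
  for (i in seq_len(n_comp)) {
    sig <- sig + amps[i] * component_channel_probs(taus[i], s)
  }
  if (!is.null(source)) {
    f <- source$intensity
    a_src <- f / (1 - f) * sum(amps)
    sig <- sig + a_src * component_channel_probs(source$lifetime, s)
  }
  sig + bg
}

#' Decompose a lifetime spectrum into discrete decay components
#'
#' Fits the convolved multi-exponential model (the same closed form as
#' [expected_spectrum()]) to a channel histogram by minimizing squared
#' Poisson deviance residuals — numerically a least-squares problem, but
#' statistically exact Poisson maximum likelihood, which matters on the
#' sparse o-Ps tail where inverse-observed-count weights are biased.
#' Lifetimes (as logs), component
#' amplitudes, the time-zero centroid, the instrument-response FWHM and the
#' flat background are all free parameters, optimized with bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). Components are sorted by
#' lifetime and intensities are reported as percent area fractions of the
#' background- and source-corrected signal.
#'
#' @param spectrum A `pals_spectrum` or data frame with `channel` and
#'   `counts` columns. If acquisition settings are not attached,
#'   `channel_width` must be supplied via `settings`.
#' @param n_components Number of decay components to fit (1 to 4; default 3:
#'   p-Ps, free positron, o-Ps).
#' @param start Optional named list overriding starting values: `lifetimes`
#'   (ns), `intensities` (fractions), `t0_channel`, `irf_fwhm` (ps),
#'   `background` (counts/channel).
#' @param source Optional source (foil) correction, a list with `lifetime`
#'   (ns) and `intensity` (fraction of signal counts); the component is held
#'   fixed and excluded from the intensity normalization.
#' @param settings Acquisition settings; defaults to the spectrum's attached
#'   metadata.
#' @param lifetime_bounds Two-row matrix (`lower`, `upper`) of lifetime
#'   bounds in ns, one column per component. Defaults encode the physical
#'   ordering p-Ps < free positron < o-Ps for the three-component case.
#'
#' @return A `pals_fit` object; see [tidy.pals_fit()] and
#'   [glance.pals_fit()]. Non-convergence is reported via the `converged`
#'   flag, not an error.
#' @export
fit_components <- function(spectrum, n_components = 3L, start = NULL,
                           source = NULL, settings = NULL,
                           lifetime_bounds = NULL) {
  if (n_components < 1L || n_components > 4L) {
    abort("`n_components` must be between 1 and 4.")
  }
  settings <- settings %||% attr(spectrum, "settings")
  if (is.null(settings)) {
    abort("No acquisition settings attached to the spectrum; pass `settings`.")
  }
  counts <- spectrum$counts
  n_comp <- as.integer(n_components)

  bg0 <- start$background %||% estimate_background(spectrum)
  if (sum(counts) - bg0 * length(counts) < 1e4) {
    abort("Spectrum must contain at least 1e4 counts above background.")
  }

  default_tau <- list(
    `1` = 1.8, `2` = c(0.40, 1.8), `3` = c(0.125, 0.40, 1.8),
    `4` = c(0.125, 0.40, 1.8, 3.0)
  )[[as.character(n_comp)]]
  default_int <- list(
    `1` = 1, `2` = c(0.90, 0.10), `3` = c(0.03, 0.88, 0.09),
    `4` = c(0.03, 0.85, 0.09, 0.03)
  )[[as.character(n_comp)]]
  tau0 <- start$lifetimes %||% default_tau
  int0 <- start$intensities %||% default_int
  int0 <- int0 / sum(int0)
  t0_0 <- start$t0_channel %||% (which.max(counts) - 1L)
  fwhm0 <- start$irf_fwhm %||% 250

  if (is.null(lifetime_bounds)) {
    lifetime_bounds <- switch(
      n_comp,
      matrix(c(0.05, 10), 2),
      matrix(c(0.1, 1.0, 0.8, 10), 2),
      matrix(c(0.05, 0.3, 0.2, 1.0, 1.0, 5.0), 2),
      matrix(c(0.05, 0.3, 0.2, 1.0, 1.0, 5.0, 1.5, 50), 2)
    )
  }
  tau0 <- pmin(pmax(tau0, lifetime_bounds[1, ]), lifetime_bounds[2, ])

  sig_counts <- sum(counts) - bg0 * length(counts)
  par0 <- c(log(tau0), int0 * sig_counts, t0_0, fwhm0, bg0)
  if (is.null(start$t0_channel)) {
    # the histogram peak sits after the time-zero centroid by the mode lag of
    # the convolved model; correct the start by that lag, evaluated once at
    # the starting parameters, so the optimizer begins in the right basin
    m0 <- fit_model_counts(par0, n_comp, settings, source)
    t0_0 <- t0_0 - ((which.max(m0) - 1L) - t0_0)
    par0[2 * n_comp + 1L] <- t0_0
  }
  lower <- c(log(lifetime_bounds[1, ]), rep(0, n_comp),
             t0_0 - 50, 20, 0)
  upper <- c(log(lifetime_bounds[2, ]), rep(2 * sum(counts), n_comp),
             t0_0 + 50, 1000, max(bg0 * 5 + 10, 50))

  # Poisson deviance residuals: minimizing their sum of squares is exact
  # Poisson maximum likelihood, which stays unbiased on the low-count tail
  # where 1/observed-count weighting drags the slow lifetime downward.
  resid_fun <- function(par) {
    m <- pmax(fit_model_counts(par, n_comp, settings, source), 1e-12)
    d <- 2 * (m - counts + ifelse(counts > 0, counts * log(counts / m), 0))
    sign(counts - m) * sqrt(pmax(d, 0))
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  # polish: restart from the solution until the deviance stops moving; the
  # objective surface is flat along the t0/IRF/fast-lifetime correlation and
  # a single Levenberg-Marquardt pass can stop short
  for (pass in 1:3) {
    refit <- minpack.lm::nls.lm(
      par = fit$par, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    )
    improved <- refit$deviance < fit$deviance - 1e-8 * abs(fit$deviance)
    fit <- refit
    if (!improved) break
  }
  converged <- fit$info %in% 1:4

  par <- fit$par
  taus <- exp(par[seq_len(n_comp)])
  amps <- par[n_comp + seq_len(n_comp)]
  ord <- order(taus)
  taus <- taus[ord]
  amps <- amps[ord]
  # merge effectively tied components rather than reporting a split doublet
  if (n_comp > 1L && any(diff(taus) / taus[-n_comp] < 1e-3)) {
    i <- which(diff(taus) / taus[-n_comp] < 1e-3)[1]
    amps[i] <- amps[i] + amps[i + 1L]
    taus <- taus[-(i + 1L)]
    amps <- amps[-(i + 1L)]
    n_eff <- length(taus)
  } else {
    n_eff <- n_comp
  }
  intens <- 100 * amps / sum(amps)
  # exact closure: the last (o-Ps) intensity absorbs rounding residue
  intens[n_eff] <- 100 - sum(intens[-n_eff])

  dof <- length(counts) - length(par)
  chi2_red <- sum(fit$fvec^2) / dof

  # parameter covariance from the local curvature of the weighted objective
  se_tau <- rep(NA_real_, n_eff)
  se_int <- rep(NA_real_, n_eff)
  # parameters resting on a bound (e.g. background 0 in a background-free
  # simulation) make the curvature singular; treat them as fixed and invert
  # the free block only
  tol_b <- 1e-8 * (1 + abs(par))
  free <- which(par > lower + tol_b & par < upper - tol_b)
  covar <- tryCatch({
    cv <- matrix(0, length(par), length(par))
    cv[free, free] <- chi2_red * 2 *
      solve(fit$hessian[free, free, drop = FALSE])
    cv
  }, error = function(e) NULL)
  if (!is.null(covar) && n_eff == n_comp) {
    idx_tau <- seq_len(n_comp)[order(exp(fit$par[seq_len(n_comp)]))]
    se_log_tau <- sqrt(pmax(diag(covar)[idx_tau], 0))
    se_tau <- taus * se_log_tau
    se_tau[!idx_tau %in% free] <- NA_real_  # pinned at a bound: unknown
    idx_amp <- (n_comp + seq_len(n_comp))[order(exp(fit$par[seq_len(n_comp)]))]
    cov_a <- covar[idx_amp, idx_amp, drop = FALSE]
    S <- sum(amps)
    J <- (diag(n_comp) * S - matrix(amps, n_comp, n_comp)) / S^2
    se_int <- 100 * sqrt(pmax(diag(J %*% cov_a %*% t(J)), 0))
    se_int[!idx_amp %in% free] <- NA_real_
  }

  structure(
    list(
      lifetimes = taus,
      intensities = intens,
      se_lifetimes = se_tau,
      se_intensities = se_int,
      signal_counts = sum(amps),
      background = par[2 * n_comp + 3L],
      t0_channel = par[2 * n_comp + 1L],
      irf_fwhm = par[2 * n_comp + 2L],
      chi2_red = chi2_red,
      converged = converged,
      info = fit$info,
      message = fit$message,
      n_components = n_eff,
      source = source,
      settings = settings
    ),
    class = "pals_fit"
  )
}

#' @export
print.pals_fit <- function(x, ...) {
  cat(sprintf("<pals_fit> %d components, reduced chi-square %.3f%s\n",
              x$n_components, x$chi2_red,
              if (x$converged) "" else " (NOT converged)"))
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  tau%d = %.4g ns (se %.2g), I%d = %.4g%% (se %.2g)\n",
                i, x$lifetimes[i], x$se_lifetimes[i],
                i, x$intensities[i], x$se_intensities[i]))
  }
  cat(sprintf("  background %.3g counts/ch, t0 %.2f ch, IRF FWHM %.0f ps\n",
              x$background, x$t0_channel, x$irf_fwhm))
  invisible(x)
}

#' Tidy a spectrum fit into one row per decay component
#'
#' @param x A `pals_fit` from [fit_components()].
#' @param ... Unused.
#' @return A tibble with columns `component`, `lifetime_ns`,
#'   `lifetime_se`, `intensity_pct`, `intensity_se`.
#' @method tidy pals_fit
#' @export
tidy.pals_fit <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    lifetime_ns = x$lifetimes,
    lifetime_se = x$se_lifetimes,
    intensity_pct = x$intensities,
    intensity_se = x$se_intensities
  )
}

#' One-row fit summary
#'
#' @param x A `pals_fit`.
#' @param ... Unused.
#' @return A tibble with the fitted background, time-zero channel, IRF FWHM,
#'   reduced chi-square, mean lifetime and convergence flag.
#' @method glance pals_fit
#' @export
glance.pals_fit <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    background = x$background,
    t0_channel = x$t0_channel,
    irf_fwhm = x$irf_fwhm,
    chi2_red = x$chi2_red,
    tau_mean_ns = mean_lifetime(x),
    converged = x$converged
  )
}

#' Intensity-weighted mean positron lifetime
#'
#' The average lifetime over all fitted components,
#' `sum(I_i * tau_i)` with intensities as fractions — the conventional
#' stability diagnostic of a PALS analysis.
#'
#' @param fit A `pals_fit`, or a data frame with `lifetime_ns` and
#'   `intensity_pct` columns (e.g. from [tidy.pals_fit()]).
#' @return Mean lifetime in ns.
#' @examples
#' mean_lifetime(data.frame(lifetime_ns = c(0.125, 0.40, 1.83),
#'                          intensity_pct = c(25, 66, 9)))
#' @export
mean_lifetime <- function(fit) {
  if (inherits(fit, "pals_fit")) {
    return(sum(fit$lifetimes * fit$intensities / 100))
  }
  if (!all(c("lifetime_ns", "intensity_pct") %in% names(fit))) {
    abort("`fit` must be a pals_fit or have lifetime_ns/intensity_pct columns.")
  }
  sum(fit$lifetime_ns * fit$intensity_pct / 100)
}
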