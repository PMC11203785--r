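#' Constants of the Tao-Eldrup free-volume chain
#'
#' @param delta_R Thickness of the electron layer on the cavity wall, in nm
#'   (default 0.1656 nm = 1.656 Angstrom, the standard calibration).
#' @param tau_limit Pick-off lifetime limit as the radius goes to zero, in ns
#'   (0.5 ns, the spin-averaged annihilation rate in the electron layer).
#' @param C Empirical dimensionless calibration of the fractional free
#'   volume; conventionally between 0.001 and 0.002 (default 0.0018).
#'   Values outside that range are accepted with a warning.
#' @param R_max Validity bound of the spherical-cavity model, in nm. The
#'   model is derived for sub-nanometer cavities; radii above `R_max` are
#'   flagged with a warning, not an error.
#' @param min_cavity_diameter Minimum cavity diameter able to host a
#'   positronium atom, in nm (0.106 nm); exposed as a documented reporting
#'   guard, not a fit constraint.
#'
#' @return An object of class `te_constants`.
#' @examples
#' te_constants()
#' @export
te_constants <- function(delta_R = 0.1656, tau_limit = 0.5, C = 0.0018,
                         R_max = 1.0, min_cavity_diameter = 0.106) {
  stopifnot(delta_R > 0, tau_limit > 0, C > 0, R_max > 0)
  if (C < 0.001 || C > 0.002) {
    warn(sprintf("C = %g lies outside the conventional 0.001-0.002 range.", C))
  }
  if (R_max > 1.0) {
    warn("R_max above 1 nm exceeds the documented validity of the spherical model.")
  }
  structure(
    list(delta_R = delta_R, tau_limit = tau_limit, C = C, R_max = R_max,
         min_cavity_diameter = min_cavity_diameter),
    class = "te_constants"
  )
}

#' o-Ps pick-off lifetime for a spherical cavity radius
#'
#' The Tao-Eldrup relation
#' \deqn{\tau_3 = 0.5\,[1 - x + \sin(2\pi x)/(2\pi)]^{-1},\quad
#'       x = R/(R + \Delta R)}
#' giving the ortho-positronium lifetime in ns for a spherical free-volume
#' radius R in nm. Strictly increasing in R.
#'
#' @param R Cavity radius in nm (vectorized; must be positive).
#' @param constants A [te_constants()] object.
#' @return Lifetimes in ns.
#' @examples
#' tau3_from_radius(0.272)   # ~1.86 ns
#' @export
tau3_from_radius <- function(R, constants = te_constants()) {
  if (any(R <= 0)) abort("Radius must be positive.")
  if (any(R > constants$R_max)) {
    warn(sprintf("Radius above R_max = %g nm: outside the spherical-model validity window.",
                 constants$R_max))
  }
  x <- R / (R + constants$delta_R)
  constants$tau_limit / (1 - x + sin(2 * pi * x) / (2 * pi))
}

#' Cavity radius from an o-Ps lifetime
#'
#' Inverts the Tao-Eldrup relation by bracketed root finding
#' ([stats::uniroot()] to a lifetime tolerance of 1e-12 ns). Defined for
#' lifetimes above the 0.5 ns pick-off limit and below the image of `R_max`.
#'
#' @param tau3 o-Ps lifetime in ns (vectorized).
#' @param constants A [te_constants()] object.
#' @return Radii in nm.
#' @examples
#' radius_from_tau3(1.83)    # ~0.269 nm
#' @export
radius_from_tau3 <- function(tau3, constants = te_constants()) {
  if (any(tau3 <= constants$tau_limit)) {
    abort(sprintf(
      "tau3 must exceed the %g ns pick-off limit (no cavity radius solves the model).",
      constants$tau_limit))
  }
  tau_max <- withCallingHandlers(
    tau3_from_radius(constants$R_max, constants),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (any(tau3 > tau_max)) {
    abort(sprintf(
      "tau3 above %.3g ns maps beyond R_max = %g nm where the spherical model is invalid.",
      tau_max, constants$R_max))
  }
  vapply(tau3, function(tt) {
    uniroot(
      function(R) {
        x <- R / (R + constants$delta_R)
        constants$tau_limit / (1 - x + sin(2 * pi * x) / (2 * pi)) - tt
      },
      lower = 1e-9, upper = constants$R_max, tol = 1e-13
    )$root
  }, numeric(1))
}

#' Spherical free-volume size
#'
#' @param R Cavity radius in nm (positive, vectorized).
#' @return Volume `(4/3) pi R^3` in nm^3.
#' @examples
#' free_volume_size(0.272)   # ~0.084 nm^3
#' @export
free_volume_size <- function(R) {
  if (any(R <= 0)) abort("Radius must be positive.")
  4 / 3 * pi * R^3
}

#' Fractional free volume
#'
#' `fv = C * Vf * I3` with the cavity volume in nm^3 and the o-Ps intensity
#' in percent — the percent convention is deliberate: it is the one under
#' which published fractional free volumes of order 1e-3 a.u. are obtained
#' (e.g. 0.0018 * 0.084 * 8.96 = 0.00135).
#'
#' @param Vf Cavity volume in nm^3 (>= 0, vectorized).
#' @param I3 o-Ps intensity in percent (>= 0).
#' @param constants A [te_constants()] object supplying `C`.
#' @return Fractional free volume (a.u.).
#' @export
fractional_free_volume <- function(Vf, I3, constants = te_constants()) {
  if (any(Vf < 0)) abort("Vf must be non-negative.")
  if (any(I3 < 0)) abort("I3 must be non-negative.")
  constants$C * Vf * I3
}

#' Full free-volume profile from o-Ps observables
#'
#' Chains the Tao-Eldrup inversion, the spherical volume and the fractional
#' free volume for a table of (tau3, I3) observations, carrying full
#' precision throughout; round only when reporting. Radii below the minimum
#' positronium cavity (diameter 0.106 nm) are flagged in `below_ps_minimum`.
#'
#' @param data A data frame with columns `tau3` (ns) and `I3` (percent);
#'   other columns (e.g. `sample`) are passed through.
#' @param constants A [te_constants()] object.
#' @return A tibble: the input columns plus `R` (nm), `Vf` (nm^3), `fv`
#'   (a.u.) and `below_ps_minimum`.
#' @examples
#' free_volume_profile(data.frame(tau3 = 1.83, I3 = 9.01))
#' @export
free_volume_profile <- function(data, constants = te_constants()) {
  if (!all(c("tau3", "I3") %in% names(data))) {
    abort("`data` must have `tau3` and `I3` columns.")
  }
  R <- radius_from_tau3(data$tau3, constants)
  Vf <- free_volume_size(R)
  dplyr::mutate(
    tibble::as_tibble(data),
    R = R,
    Vf = Vf,
    fv = fractional_free_volume(Vf, .data$I3, constants),
    below_ps_minimum = R < constants$min_cavity_diameter / 2
  )
}
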