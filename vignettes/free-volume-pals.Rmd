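---
title: "Free-volume analysis of positron lifetime spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-volume analysis of positron lifetime spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palsfv)
library(dplyr)
```

## The measurement and its model

Positron annihilation lifetime spectroscopy (PALS) histograms the time
between a positron's birth signal and the detection of its annihilation
photons. In molecular solids and soft matter the histogram decomposes into
a small number of exponential components. The conventional three-component
picture, which this package implements, assigns

* $\tau_1 \approx 0.125$ ns to para-positronium (p-Ps) self-annihilation,
* $\tau_2 \approx 0.4$ ns to free-positron annihilation, and
* $\tau_3 \approx 1.8\!-\!2.1$ ns to ortho-positronium (o-Ps) pick-off
  annihilation inside open (free-volume) cavities.

The o-Ps component is the carrier of structural information: the larger the
cavity, the less frequently the trapped o-Ps overlaps the surrounding
electron layer and the longer $\tau_3$ becomes, while its relative
intensity $I_3$ tracks how many such cavities are available. Positronium
forms with spin statistics of 1:3, so the p-Ps intensity is tied to the
o-Ps intensity by $I_1 = I_3/3$; `truth_from_row()` uses exactly this rule
to expand a measured $(\tau_3, I_3)$ pair into a full simulation truth.

A recorded spectrum is not a bare sum of exponentials. Each decay is
convolved with the spectrometer's timing resolution, sits on a flat random
background, and is counted with Poisson noise. `expected_spectrum()`
evaluates the noiseless model analytically: each component is an
exponential starting at the time-zero centroid convolved with a Gaussian
instrument response function (IRF), i.e. an exponentially modified
Gaussian, integrated channel by channel via its closed-form CDF. The
closed form (evaluated on the log scale where the exponential factor and
the normal tail nearly cancel) keeps the model exact and testable — there
is no FFT grid error to reason about. Each component is renormalized over
the finite acquisition window, so the expected channel sum equals the
requested total counts even for slow components whose tails leave the
window.

`simulate_spectrum()` draws each channel from a Poisson law with that mean,
reproducibly under a seed. The simulator is first-class, tested code: it
is what makes every downstream stage verifiable against a known truth.

### Acquisition defaults

The defaults of `acquisition()` describe a fast-fast coincidence
spectrometer measuring at normal statistics: 6.5 ps channels, 8192
channels (a 53 ns window), and $10^6$ counts under the curve. Two
quantities the instrument itself defines are not knowable from a published
table and are therefore explicit, configurable model choices here:

* **IRF width** — a single Gaussian with FWHM 250 ps, a conventional
  resolution for BaF$_2$-based coincidence systems;
* **time-zero position** — channel 1000, leaving a pre-peak region that
  `estimate_background()` uses for a robust (median) background estimate.

A source correction — annihilation in the Kapton foil that wraps the
positron source — is modeled, when enabled, as one extra exponential
component with configurable lifetime and intensity (0.382 ns and 10% are
literature-conventional values). It is off by default since correction
parameters are spectrometer-specific.

## Decomposition

`fit_components()` refits the same closed-form model to a measured or
simulated histogram. Free parameters are the (log) lifetimes, one
amplitude per component, the time-zero centroid, the IRF width and the
flat background; optimization is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`).

The objective is the sum of squared **Poisson deviance residuals**, which
makes the least-squares machinery minimize the exact Poisson negative
log-likelihood. This choice is deliberate and is worth a paragraph: the
o-Ps tail of a $10^6$-count spectrum holds only a few counts per channel,
and there the popular shortcut of weighting squared residuals by
1/observed count systematically drags the slow lifetime down (downward
fluctuations get the largest weights), while weighting by the model count
biases it up — both by several percent at the default conditions, which
is far beyond the reproducibility this analysis needs. The likelihood
objective is unbiased at the percent level, and the parameter-recovery
tests against the simulator's known truth (20 seeded spectra; each
recovered $\tau_3$ within 2%, mean bias below 1%, seed-to-seed CV below
the replicate CV of comparable measurements) enforce exactly that.

Two numerical details matter for convergence. First, the histogram peak
lags the time-zero centroid by the mode lag of the convolved model, so the
fitter corrects its $t_0$ starting value by that lag (evaluated once at
the starting parameters) instead of starting at the raw peak. Second, the
objective surface is flat along the correlated
$t_0$/IRF-width/fast-lifetime direction, so the optimizer restarts from
its own solution until the deviance stops improving. Starting values
($\tau = 0.125, 0.40, 1.8$ ns; $I = 3, 88, 9$%) and lifetime bounds
($\tau_1 \in [0.05, 0.3]$, $\tau_2 \in [0.2, 1.0]$,
$\tau_3 \in [1.0, 5.0]$ ns) encode the fixed physical ordering of the
three annihilation channels; components are re-sorted after the fit and
effectively tied lifetimes are merged rather than reported as a split
doublet. Intensities are area fractions of the background- and
source-corrected signal, closed to exactly 100%. Uncertainties come from
the local curvature of the objective at the optimum; non-convergence is
reported as a flag with diagnostics, not an error.

One wrinkle of the field's vocabulary: intensity is sometimes written as
an amplitude-to-lifetime ratio ($I = A/\tau$ with $A$ the component area
in counts·time units). For a normalized exponential these are the same
number up to the total-area normalization; this package reports the
standard area-fraction definition throughout.

```{r fit-example}
s <- acquisition(total_counts = 2e5, n_channels = 2048, channel_width = 26,
                 t0_channel = 300)
truth <- truth_from_row(tau3 = 1.83, I3 = 9.01, seed = 42)
sp <- simulate_spectrum(s, truth)
fit <- fit_components(sp)
tidy(fit)
glance(fit)
```

## The Tao–Eldrup chain

The o-Ps pick-off lifetime maps to a mean cavity radius through the
Tao–Eldrup model of a positronium in a spherical well whose wall carries
an electron layer of thickness $\Delta R = 0.1656$ nm:

$$\tau_3 \,[\mathrm{ns}] = 0.5\left[1 - \frac{R}{R+\Delta R}
  + \frac{1}{2\pi}\sin\!\left(\frac{2\pi R}{R+\Delta R}\right)\right]^{-1}.$$

The prefactor 0.5 ns is the $R \to 0$ limit (spin-averaged annihilation
entirely inside the electron layer), so lifetimes at or below 0.5 ns have
no solution and are rejected. The model is valid for sub-nanometer radii;
`te_constants()` exposes the validity bound `R_max = 1` nm and radii above
it produce warnings rather than errors. The forward map is strictly
increasing, so `radius_from_tau3()` inverts it by bracketed root finding
(`stats::uniroot`, lifetime tolerance $10^{-12}$ ns); round-trips are
identities to better than $10^{-9}$ nm across the practical lifetime
window, and the inverse is cross-checked in the tests against an
independent dense-grid interpolation oracle.

From the radius follow the spherical cavity volume $V_f = \frac{4}{3}\pi
R^3$ and the fractional free volume $f_v = C\,V_f\,I_3$ with the empirical
calibration $C = 0.0018$ (dimensionless, conventionally 0.001–0.002).
**$I_3$ enters in percent, not as a fraction.** This convention is easy to
get wrong and matters at the factor-100 level; it is the one under which
published skin free-volume tables (e.g. $0.0018 \times 0.084 \times 8.96
= 0.00135$) reproduce cell by cell, and such tabulated values are often
quoted $\times 10^3$ elsewhere (0.00135 as "1.35 a.u."). The chain in
`free_volume_profile()` computes at full precision and leaves rounding to
the caller; a cavity radius below the minimum positronium-hosting cavity
(diameter 0.106 nm) is flagged, not clamped.

```{r te-example}
free_volume_profile(skin_reference()) |>
  select(sample, tau3, I3, R, Vf, fv) |>
  mutate(across(c(R, Vf), ~ round(.x, 3)), fv = round(fv, 5))
```

Note the rounding interplay visible in such tables: a published
fractional-free-volume column computed from a volume already rounded to
3 decimals can differ by one unit in the fifth decimal from the
full-precision chain, and a radius printed to 3 decimals can disagree with
the inversion of a lifetime itself printed to only 2 (sample IV here:
inverting 1.84 ns gives 0.270 nm at full precision, while 0.269 was
evidently obtained from an unrounded lifetime).

## Replicate statistics

`summarize_replicates()` reduces per-sample rows to mean, $n-1$ standard
deviation and CV$\% = 100\,\mathrm{SD}/\mathrm{mean}$ per parameter. A
point of honesty in reporting: a CV computed over per-sample means is
systematically smaller than a CV over all raw repetitions (the former
averages away within-sample scatter), so the summary carries an explicit
`basis` label and the two are never comparable. With only the per-sample
means of a published table available, the repetition-level CVs of the
original measurements cannot be recomputed — the tests assert exactly
that the row-basis CV is smaller.

`normality_check()` delegates Shapiro–Wilk to `stats::shapiro.test()` and
attaches the decision at $\alpha$ (normal iff $p > \alpha$).
`stability_series()` screens long acquisition sessions for drift by
regressing each parameter on measurement time per sample and flagging
slopes beyond 3 standard errors; the 3-SE default keeps the joint
false-alarm rate over two monitored parameters near 2% for 15-point
series while retaining high power for a 10% drift over the session. The
flagging rule is this package's own, since stability in such protocols is
usually asserted visually.

## The pipeline

`run_pipeline()` chains simulate (or read) → fit → free-volume →
summarize and writes a report bundle (fit CSV, free-volume CSV, summary
CSV, a normality block and a run log echoing configuration, seeds and
package version). Repetition $r$ of sample $s$ uses seed
$\mathrm{base} + 1000s + r$, so any single spectrum can be regenerated in
isolation; with a fixed configuration the deterministic outputs are
byte-identical across reruns. Channel indices are 0-based and times are
channel-center based, $t = (\mathrm{channel} - t_0)\cdot w$; every
spectrum file header states this so no coordinate ambiguity survives a
round-trip. A failing stage aborts with the stage named and removes
partial outputs.

## What the simulator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
multi-exponential decay, Gaussian IRF, flat background, Poisson counting
noise, optional foil term. It does not model detector pile-up, gain or
time-zero drift, non-Gaussian IRF tails, 2γ/3γ branching physics, or
continuous lifetime distributions. Passing parameter-recovery tests
therefore demonstrate that the decomposition is correct and unbiased
*under the stated noise model* — they do not certify performance against
instrument pathologies a real spectrometer may add, which is also why the
package's fitted IRF width and $t_0$ are free per spectrum rather than
fixed.

Problem sizes used by the test suite reflect a deliberate split: unit
tests run on coarse geometries (1024–2048 channels of 26 ps, $10^5$
counts) where a fit takes well under a second, while the acceptance-level
recovery and end-to-end checks run at the full acquisition geometry
(8192 × 6.5 ps, $10^6$ counts) with 20 seeded recovery fits and an
11-sample × 3-repetition pipeline. The noiseless self-consistency check
uses $10^8$ counts, because rounding a model curve to integers truncates
the sub-0.5-count tail and at lower statistics that truncation — not the
fitter — limits the recovered accuracy.

## Known limitations

* Discrete components only; no CONTIN/MELT-style continuous lifetime
  distribution inversion.
* The spherical Tao–Eldrup form only; no extended variants for mesopores,
  no temperature dependence.
* The source correction is a single fixed exponential; real foil
  corrections sometimes use two terms.
* Uncertainties are curvature-based (local, symmetric); no profile
  likelihood or bootstrap.
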