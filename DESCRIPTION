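Package: palsfv
Title: Free-Volume Analysis of Positron Annihilation Lifetime Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for positron annihilation lifetime spectroscopy (PALS)
    free-volume studies of soft matter such as stratum corneum lipid
    bilayers. Simulates channel-histogram lifetime spectra as multi-
    exponential decays convolved with a Gaussian instrument response under
    Poisson counting statistics, decomposes measured or simulated spectra
    into p-Ps, free-positron and o-Ps components by Poisson-weighted
    nonlinear least squares, converts the o-Ps lifetime and intensity into
    free-volume radius, cavity volume and fractional free volume through
    the Tao-Eldrup model, and aggregates replicate measurements into
    mean/CV summaries with normality and stability diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
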