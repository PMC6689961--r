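Package: eqnoise
Title: Equivalent-Noise Analysis of Contour Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for equivalent-noise psychophysics of contour integration:
    parametric log-Gabor contour stimuli with external orientation noise, a
    simulated observer for the four-alternative forced-choice good-continuation
    task, a 2-down-1-up adaptive staircase, Gumbel psychometric-function
    fitting with principled removal of unreliable high-amplitude points,
    Linear Amplifier Model estimation of internal noise and integration
    efficiency, and rank-based Wald-type inference for mixed factorial
    designs (group by visual-field quadrant), together with a synthetic-cohort
    generator so the full pipeline runs end to end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr,
    readr
Config/testthat/edition: 3
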