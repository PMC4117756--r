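Package: unwindr
Title: Simulation and Kinetic Analysis of Repetitive Helicase Unwinding
    from Single-Molecule FRET Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for single-molecule FRET (smFRET) studies of repetitive
    RNA unwinding by RNA helicase A (RHA/DHX9). Provides a stochastic
    simulator of the five-substep kinetic cycle (binding, activation,
    unwinding, stalling, reactivation) that emits ground-truthed
    donor/acceptor intensity traces with protein-induced fluorescence
    enhancement, photobleaching and strand-separation events; trace
    processing (FRET/total-intensity series, bleach and binding/dissociation
    step detection, population FRET histograms); substep idealization with
    censored dwell-time extraction and cycle counting; and rate inference
    (exponential dwell-time rate estimates with SEM, zero-intercept
    association-constant fits, Michaelis-Menten ATP fits, binding isotherms,
    temperature fold-changes) together with annealing time-course analysis
    and the unwinding-vs-binding annealing enhancement factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
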