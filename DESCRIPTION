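Package: maizersa
Title: Stochastic 3D Simulation of Maize Root System Architecture Under
    Strigolactone Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stochastic three-dimensional root system architectures
    (RSAs) of maize from literature-derived trait distributions. Main root
    axes (primary, seminal, crown, brace) elongate along a negative-
    exponential growth law and branch into lateral roots through threshold
    stochastic rules. Strigolactone (GR24) concentration modulates axis
    elongation and lateral branching density through piecewise-linear
    dose-response multipliers. Includes Monte-Carlo ensemble phenotyping
    (medians, bootstrap confidence intervals, wild-type normalisation,
    dose sweeps), RSML and CSV export, configuration files, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
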