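Package: pmburden
Title: Ambient PM2.5 Mortality Burden under WHO Air Quality Guideline Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative risk assessment pipeline for the mortality burden
    attributable to ambient fine particulate matter (PM2.5). Evaluates
    nonlinear exposure-response curves (integrated exposure-response, IER;
    Global Exposure Mortality Model, GEMM, as an alternative), converts
    relative risks to population attributable fractions, combines gridded
    population-weighted exposures with baseline cause-specific mortality,
    and quantifies the reduction in attributable deaths when grid-cell
    exposures are capped at the WHO interim targets (35/25/15 ug/m3) and
    the air quality guideline level (10 ug/m3), with matched-draw Monte
    Carlo uncertainty intervals. Includes a synthetic-world generator so
    the full pipeline runs and is tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
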