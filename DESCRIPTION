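Package: circaseason
Title: Seasonal Circadian Rhythmometry of Clock-Gene Expression and Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing seasonal variation in morning clock-gene
    expression and its coupling to wrist-actigraphy rhythms at high latitude.
    Implements single- and multi-component cosinor rhythmometry (MESOR,
    amplitude, acrophase, zero-amplitude test), non-parametric circadian
    metrics (inter-daily stability, intra-daily variability, M10/L5, relative
    amplitude, circadian function index), relative expression quantification
    by the 2^-ddCq method, clock-time windowed correlation mapping with
    Benjamini-Hochberg false-discovery control and harmonic peak modelling,
    seasonal comparisons with Tukey post hoc tests, and sigma-restricted
    general linear models reporting standardized coefficients, partial
    eta-squared and observed power. A synthetic-cohort generator emulates
    Arctic photoperiods, circadian activity and temperature structure, and
    light-coupled expression with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
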