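Package: concindex
Title: Concentration Indices and Wagstaff Decomposition of Inequality in
    Maternal Health Care Utilisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures socioeconomic inequality in binary health-care
    utilisation indicators from woman-level survey microdata.  Computes
    weighted fractional ranks (Lerman-Yitzhaki midpoints), the
    concentration index as twice the weighted covariance between outcome
    and rank over the mean, concentration-curve coordinates with an exact
    twice-area oracle, and Wagstaff-type decompositions of the index into
    per-covariate contributions (elasticity times the covariate's own
    concentration index) plus a generalised-concentration-index residual.
    Includes maternal-care indicator recodes (full antenatal care, skilled
    birth attendance, postnatal care), poor/non-poor gap tables, state-wise
    indices, a configurable generator of NFHS-like synthetic survey
    microdata with planted wealth gradients, and a config-driven pipeline
    that writes all report tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
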