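Package: mirdose
Title: Preclinical-to-Clinical Radioimmunoconjugate Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: MIRD-schema internal dosimetry for radioimmunoconjugate
    development: converts per-animal biodistribution tables (percent
    injected dose per gram) into time-integrated activities (trapezoidal
    AUC plus physical-decay tail), applies user-supplied S-value tables
    and a sphere self-dose model to obtain mouse organ and tumour
    equivalent doses, and projects human organ doses by the percent
    kilogram-per-gram interspecies method. Also provides saturation
    radioligand-binding analysis (one-site Kd/Bmax fits, receptors per
    cell), exact small-sample rank-sum tests for biodistribution
    comparisons, and seeded synthetic-data generators for every pipeline
    stage.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
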