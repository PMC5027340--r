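Package: epimapr
Title: Epicardial Multielectrode Mapping and Hypertension-Study Endpoint Analysis
Version: 0.1.0
Authors@R:
    person("Mapping", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for epicardial multielectrode array (MEA)
    recordings and longitudinal cohort endpoints from large-animal
    hypertension studies. Provides a synthetic-data module that emulates a
    128-channel flexible MEA (2.7 mm pitch, 25 kHz, 12-bit) and an
    angiotensin-II ovine cohort; activation and repolarization detection
    from unipolar electrograms; activation recovery intervals (ARI);
    triangle-based conduction velocity vectors and wave propagation
    velocity (WPV); phase maps and the conduction heterogeneity index
    CHI = (P95 - P5)/P50; and group endpoint statistics (Student's t,
    percent changes, MAP trajectory characterization) with a command-line
    interface binding the stages into one reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
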