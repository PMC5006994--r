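Package: gmetkit
Title: Quality-Control-Driven Processing of Untargeted LC-MS Metabolomics
    Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quality-control-centred processing of global
    (untargeted) LC-MS metabolomics feature tables: reference-QC based
    correction of multiplicative sensitivity drift within and between
    96-well plates, repeatability and dilution-series feature filtering
    with study and dilution QC injections, storage-time trendline
    modelling of plasma quality-marker metabolites, a 40-marker plasma
    quality score with pass/fail triage, orthogonal projections to latent
    structures discriminant analysis (OPLS-DA) with S-plot feature
    selection, and a synthetic-data generator that reproduces the plate
    layout, injection sequence and drift structure the protocol assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
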