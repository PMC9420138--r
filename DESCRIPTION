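Package: wqharmonize
Title: Harmonization of Heterogeneous Nutrient Water-Quality Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw, result-level nutrient monitoring records exported in
    Water Quality Portal (WQP) style into a standardized daily concentration
    dataset. Implements a nineteen-step harmonization cascade: organization
    name standardization, monitoring-site deduplication (coordinate merging
    within a distance threshold and Monitoring Location Identifier collapse),
    a metadata-driven keep/drop filter cascade, chemical-form inference and
    molecular-to-elemental conversion, concentration-unit conversion to mg/L,
    detection-limit approximation for non-detects, Bayesian multiple
    imputation of left-censored concentrations under a lognormal model,
    percentile outlier flagging, daily duplicate averaging, sample-fraction
    combination into total nutrients, and a filtered-versus-unfiltered
    consistency check. Ships a synthetic raw-record generator with a latent
    truth sidecar so the full pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
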