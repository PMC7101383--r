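Package: plastisize
Title: Allometric Scaling of Ingestible Plastic Size and Zooplankton Risk Mapping
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-analyses of plastic ingestion by animals. Fits the
    log10-log10 allometric relationship between animal body length and the
    longest ingestible plastic fragment, with confidence and prediction
    intervals; validates the relationship by repeated random hold-out
    resampling (RMSE, interval coverage, pooled predicted-versus-observed
    regression); generates synthetic taxon-record datasets with calibrated
    noise so the whole pipeline is testable without field data; and maps
    plastic-ingestion risk for zooplankton by linearising exponential
    class grids and forming the ingestible-plastic to zooplankton-density
    ratio. A command-line entry point chains the stages.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
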