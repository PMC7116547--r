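Package: pm25grid
Title: Multi-Stage Random-Forest Reconstruction of Daily PM2.5 Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a four-stage random-forest framework that reconstructs
    daily fine-particulate (PM2.5) concentrations on a 1 km grid from a monitor
    network, gap-filled satellite aerosol optical depth (AOD), a
    chemical-transport-model surface, meteorology and geospatial predictors.
    Stage-1 augments sparse PM2.5 monitor series from co-located PM10; Stage-2
    imputes cloud-masked satellite AOD from coarse multi-wavelength reanalysis
    AOD; Stage-3 fits a per-year log-PM2.5 prediction model over 15
    spatio-temporal and 27 spatial predictors; Stage-4 applies it to every grid
    cell and day. Includes monitor-network quality control, inverse-distance
    weighted leave-one-out spatially lagged features, monitor-grouped 10-fold
    cross-validation with a spatial/temporal performance decomposition, and a
    fully synthetic study-region generator used to exercise the pipeline
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
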