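Package: duoscope
Title: Dual-Channel Miniscope Analysis: Longitudinal Cell Tracking and
    Place-Cell Drift on a Linear Track
Version: 0.1.0
Authors@R:
    person("Duoscope", "Developers", email = "duoscope@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-channel single-photon calcium
    imaging in which a dynamic indicator (GCaMP) is imaged alongside a
    constitutively expressed static nuclear marker (dTomato).  Provides
    cell detection on the static channel, centroid-distance registration
    of cells across channels and across recording sessions, quantification
    of fluorescence cross-talk between channels (observed linear
    coefficient, circular-shuffle null, and expected ratio from emission
    spectra), longitudinal tracking statistics (per-session tracking
    probability, reactivation rate), and hippocampal place-cell analysis
    on a linear track (kernel-density rate maps, spatial information,
    stability, shuffle-based classification, population-vector
    correlation).  Includes a synthetic dual-channel data generator with
    known ground truth so the full pipeline is testable without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
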