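Package: fiberpnn
Title: Fiber Photometry Calcium Signal Processing and Perineuronal Net
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for two-channel (470 nm signal / 415 nm
    isosbestic) fiber photometry recordings of population calcium activity:
    biexponential photobleaching correction, linear scaling of the
    isosbestic reference, dF/F computation, home-cage baseline correction,
    behaviour-epoch alignment with minimum-bout filtering, and per-epoch
    trace metrics (area under the curve, peak frequency, mean peak height).
    Also quantifies perineuronal-net density and surface contiguity
    (largest-connected-component fraction of a binarized WFA mask) from
    image stacks, and provides two-group estimation statistics (Cohen's d
    with bias-corrected and accelerated bootstrap confidence intervals).
    Ships a ground-truthed synthetic-data generator for every input kind so
    the full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
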