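Package: broodetect
Title: Detection of Parental Brooding in Lapwing Chicks from Multisensor Dataloggers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect parental brooding bouts in precocial chicks from
    miniature body-mounted dataloggers recording tri-axial acceleration (25 Hz),
    on-body temperature (1 Hz) and light level (1 Hz). The pipeline
    autocalibrates the accelerometer, derives overall dynamic body acceleration
    (ODBA) with median high- and low-pass filters, aggregates to 5-s bins,
    segments each chick's ODBA series with an unsupervised two-state Gaussian
    hidden Markov model, and converts non-active segments into brooding bouts
    with a rule chain (50 lx daylight rule, temperature-difference boundary
    adjustment, pruning of bouts and gaps up to 20 s). It also builds
    model-ready hourly brooding-rate and brooding-efficiency tables, renders
    actograms, simulates synthetic multichannel recordings with ground-truth
    behavioural states, and scores detections against that truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
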