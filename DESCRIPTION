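Package: rumipress
Title: Behavior Detection from Reticular Pressure Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cow behaviors (rumination, eating, drinking,
    sleeping) from reticular pressure time series sampled every 0.5 seconds.
    Implements a rule-based peak-detection algorithm that finds sharp pressure
    peaks, groups them into contraction cycles and flags rumination from the
    triphasic contraction signature, and a sliding-window spectral-feature
    pipeline (Fourier magnitudes, band power, autocorrelation) feeding
    one-vs-all random-forest classifiers with class rebalancing and three
    validation schemes (70/30 hold-out, stratified 5-fold cross-validation,
    leave-one-animal-out). A synthetic session generator emulates biphasic and
    triphasic reticular contraction cycles with behavior-specific inter-cycle
    interval distributions so the full pipeline is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
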