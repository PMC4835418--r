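Package: oxloop
Title: Simulated Pulse Oximetry and Closed-Loop Oxygen Titration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico model of a portable automated oxygen administration
    system. Synthesizes two-wavelength multiplexed photoplethysmography (PPG)
    streams with known ground-truth physiology, demultiplexes and filters them
    with a streaming IIR/FIR cascade, estimates oxygen saturation (ratio-of-
    ratios calibration), heart rate and perfusion index once per second, and
    closes the loop with a per-minute oxygen titration controller targeting
    94-98% saturation against a first-order virtual patient. Includes session
    logging, a transport-loss model, and watchdog fault handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
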