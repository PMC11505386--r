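Package: ecco2rsim
Title: Closed-Loop Sweep-Gas Control Simulation for Extracorporeal CO2 Removal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale simulator of a wearable extracorporeal CO2 removal
    (ECCO2R) system that regulates exhaust-gas CO2 (EGCO2) by closed-loop
    modulation of the sweep gas through a membrane lung. Provides a
    lumped-parameter model of the in vitro test circuit (well-mixed reservoir,
    conditioning lung, artificial lung with a single-transfer-unit gas-side
    exchange model), models of the blower pair, flow sensor and side-stream
    CO2 sensor with transport delay, a velocity-form PI controller with
    min-flow clamping and fixed-sweep mode, supervisory fault detection with
    fixed-sweep fallback, scenario protocols emulating stepped metabolic
    challenges, and step-response metrics (settling time, overshoot,
    steady-state statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
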