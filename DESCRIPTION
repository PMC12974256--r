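Package: lumicdc
Title: Behavioral Simulation of a Luminescence Current-to-Digital Converter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Clock-cycle-accurate behavioral model of a ratiometric
    time-domain dual-lifetime-referencing (t-DLR) luminescence readout for
    transcutaneous CO2 sensing and of its direct current-to-digital
    converter (CDC). Includes closed-form photophysics of a dual-luminophore
    sensing film (Stern-Volmer quenching, area integrals, luminescence-ratio
    inversion), a charge-balancing delta-sigma conversion loop with a latch
    comparator, a dynamic-element-matched current DAC and a 16-bit counter,
    the current-scaling code-selection algorithm with 100-cycle averaging,
    an analytic error budget (quantization, comparator offset and noise),
    and experiment drivers that reproduce the characterization sweeps on
    synthetic signals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
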