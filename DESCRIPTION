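Package: painephys
Title: Event-Locked LFP, Single-Unit and Nociceptive Behavior Analysis
Version: 0.1.0
Authors@R:
    person("painephys", "developers", email = "maintainer@painephys.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in-vivo basal-forebrain tetrode recordings
    during nociceptive testing. Computes event-locked, baseline-normalized
    Morlet wavelet spectrograms of the local field potential with band-power
    summaries and time courses; detects stimulation-responsive single units
    by z-scoring peri-stimulus time histograms against pre-stimulation
    baselines; classifies units into broad and narrow waveform classes;
    quantifies von Frey (Dixon up-down), Hargreaves and nocifensive-duration
    behavioral readouts; and provides the statistical battery used for these
    readouts. Ships a synthetic-data generator emulating the recording
    structure so the full pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
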