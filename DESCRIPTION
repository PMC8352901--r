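Package: clockstim
Title: Effective Circadian Clock Models Under External Stimuli
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of an effective circadian clock model:
    the five-variable PER mRNA/protein limit-cycle oscillator extended by
    bilinear external-stimulus terms (light-driven mRNA decay, PER protein
    degradation, light-induced transcription) and an input-output interface
    that couples oscillators by feeding one oscillator's state into
    another's stimulus port.  Includes the measurement procedures used in
    chronobiology: peak-based period estimation, circular phase-shift
    estimation, arrhythmicity detection, constant-light period scans
    (Aschoff's rule), phase-response curves and entrainment-range scans,
    plus experiment presets, a YAML configuration layer and TSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
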