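Package: bistream
Title: Simulation and Analysis of Bistable Auditory Streaming with
    Triplet-Locked Neural Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking continuous perceptual reports of auditory
    streaming (integrated vs. segregated hearing of repeating HLH- tone
    triplets) to triplet-locked neural source waveforms. Includes a
    synthetic-cohort generator (stimulus timelines, log-normal percept
    phase dynamics, evoked source waveforms with a configurable
    segregation signature), FIR windowed-sinc preprocessing, press-guarded
    epoching, behavioral phase statistics on transformed scales,
    cluster-based permutation testing of percept-conditional evoked
    responses, per-participant linear-SVM percept decoding with
    Haufe-corrected feature weights, and report-weighted expected-versus-
    observed tests of response bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
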