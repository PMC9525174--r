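Package: spikehist
Title: History Dependence of Sound Onset and Offset Responses in Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying short-term history dependence of
    sound-evoked (onset) and sound-termination (offset) spiking responses in
    auditory cortex recordings. Builds peristimulus time histograms (PSTHs)
    from per-trial spike times, screens units for stimulus-locked firing with
    a split-half reliability score against a shuffled-interspike-interval
    permutation null, detects unambiguous onset and offset responses with a
    three-threshold rule, and summarises response dynamics with a
    facilitation-depression index (FDI) computed under several subtraction
    methods. Includes waveform-based narrow/broad-spiking classification,
    four-criterion opto-tagging, recording-site quality gates (multiunit
    threshold crossings, frequency-tuning tests, primary-like latencies,
    fractional cortical depth), firing-rate distribution matching, template
    matching of response dynamics, correlation-distance hierarchical
    clustering of normalized PSTHs, and a seeded inhomogeneous-Poisson
    spike-train generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
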