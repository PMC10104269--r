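Package: aqueductflow
Title: Oscillatory Cerebral-Aqueduct Flow: Similarity Scaling, Womersley
    Pressure Modelling and Transmantle Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the oscillatory cerebrospinal-fluid flow
    through the cerebral aqueduct and the interventricular (transmantle)
    pressure difference that drives it.  Provides the dimensionless framework
    (Womersley number, stroke length, cycle-averaged pressure magnitude and
    flow/pressure phase lag), Buckingham-Pi similarity design of scaled
    in-vitro experiments including glycerol-water working-fluid selection, a
    harmonic-superposition Womersley flow model with an entrance-loss term and
    an optional quasi-one-dimensional variable-area treatment, a
    signal-processing pipeline from raw pump/transducer recordings (Hampel
    despiking, zero-phase low-pass filtering, piston differentiation,
    FFT-fundamental phase estimation) to cycle-averaged dimensionless
    summaries, a synthetic recording simulator, and a clinical estimator of
    the mean transmantle pressure fluctuation from MRI-measurable stroke
    volume, heart rate and aqueduct anatomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
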