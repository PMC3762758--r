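Package: hybridBCI
Title: Hybrid Brain-Computer Interface Decoding and Closed-Loop Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decoding toolkit for a low-cost hybrid electroencephalography (EEG)
    brain-computer interface combining three two-class protocols: motor-imagery
    event-related desynchronization decoded with Common Spatial Patterns and a
    linear max-margin classifier, steady-state visually evoked potentials decoded
    by canonical correlation against sinusoidal references at 12 and 15 Hz, and
    P300 evoked potentials decoded with xDAWN spatial filtering and Bayesian
    linear discriminant analysis. Includes the correlation-space arbiter that
    selects between the motor-imagery and visual protocols, the fading-feedback
    command confirmation rule, a synthetic EEG generator with protocol-specific
    structure, Wolpaw information-transfer-rate and cross-validation utilities,
    and a closed-loop simulated humanoid surrogate with a toy vision stage for
    end-to-end exercises without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'cca.R'
    'closedloop.R'
    'csp.R'
    'eval.R'
    'filtering.R'
    'hybrid.R'
    'io-csv.R'
    'io-edf.R'
    'p300.R'
    'serialize.R'
    'surrogate.R'
    'synth.R'
    'utils.R'
    'vision.R'
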