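Package: speechPAC
Title: Speech-Brain Entrainment and Theta-Gamma Phase-Amplitude Coupling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cortical tracking of speech rhythms in
    M/EEG-type recordings. Extracts the wideband amplitude envelope of speech
    through a gammatone (cochlear) filterbank, quantifies low-frequency
    speech-brain entrainment by Welch magnitude-squared coherence on a 0.5 Hz
    grid, and quantifies theta-gamma phase-amplitude coupling by mutual
    information between equipopulated-binned phase and amplitude dynamics with
    quadratic-extrapolation bias correction. Chance levels are estimated from
    reversed-stimulus surrogates and group effects are assessed with
    cluster-corrected paired sign-flip permutation tests. A seeded synthetic
    cohort generator with known entrainment and coupling ground truth drives
    validation, including speech-rate (tempo) manipulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'io.R'
    'filters.R'
    'synthetic.R'
    'envelope.R'
    'entrainment.R'
    'pac.R'
    'groupstats.R'
    'pipeline.R'
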