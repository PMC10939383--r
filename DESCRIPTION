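Package: voxdesign
Title: Fixed-Backbone Protein Sequence Design with 3D Convolutional
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxelises protein backbone microenvironments into
    canonically oriented density frames, trains and applies compact 3D
    convolutional neural network residue classifiers (including
    polarity and charge constraint channels), samples sequences from
    the predicted per-residue probability distributions by
    temperature-scaled Monte Carlo, and evaluates designs with a suite
    of sequence-recovery and shape metrics (macro-recall, prediction
    bias, charge and isoelectric-point error, Shannon entropy, Kabsch
    RMSD and length-normalised RMSD100, backbone packing density).
    Includes an ideal-geometry backbone generator so the whole pipeline
    is testable without external structure data, and a command-line
    front end for batch voxelisation, training, design and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    optparse,
    seqinr,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
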