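Package: egnnqa
Title: Protein Model Quality Assessment with an Equivariant Graph Network Confidence Head
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Superposition-free local distance difference test (LDDT) scoring of
    predicted protein structures against a reference, in both C-alpha and
    all-heavy-atom variants, together with a trainable per-residue confidence
    (pLDDT) head built from E(n)-equivariant graph convolutional layers over a
    16 Angstrom C-alpha contact graph. The head consumes single-representation,
    pair-representation and language-model embedding tensors plus ensemble
    root-mean-square-fluctuation features, emits a 50-bin LDDT distribution per
    residue, and is trained with a bin-frequency-weighted cross-entropy loss.
    Includes ensemble superposition and RMSF computation, a synthetic-structure
    generator with known ground-truth LDDT for end-to-end testing, an
    evaluation protocol (per-model and per-residue errors, category confusion
    matrices, win/tie/loss comparisons, chi-squared category tests), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
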