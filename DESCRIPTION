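Package: duplexmech
Title: Sequence-Dependent Shape and Nonlocal Harmonic Stiffness of DNA and
    RNA Double Helices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid-base modelling of DNA and RNA double helices at the
    hexanucleotide scale. Predicts sequence-dependent shape (intra-basepair,
    step and groove-width profiles), per-coordinate stiffness, and a nonlocal
    banded stiffness matrix assembled from overlapping 66x66 hexameric blocks,
    with eigenvalue-cutoff repair and band trimming. Estimates model
    parameters from coordinate ensembles via maximum-absolute-entropy banded
    precision matrices, derives global material constants (stretch modulus,
    twist stiffness, twist-stretch coupling, bending and twist persistence
    lengths, static disorder, length-scale profiles), threads per-step
    templates to score deformation energies, designs minimal sequences
    covering every k-mer class, and ships a synthetic parameter generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
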