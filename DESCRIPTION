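Package: compDTA
Title: Drug-Target Binding Affinity Prediction with Alignment- and
    Compression-Based Protein Encoding
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts drug-target binding affinities from protein sequences
    and ligand SMILES strings. Proteins are encoded against a reference panel
    by a unified similarity measure: the entrywise (Hadamard) product of a
    normalized Smith-Waterman local-alignment similarity and an LZMA
    normalized-compression-distance similarity. The encoded proteins and
    label-encoded SMILES feed a light two-branch neural regressor (a
    fully-connected protein branch and an embedding + CNN + separable-CNN
    drug branch). Includes flat-file readers, affinity harmonization,
    warm/cold-start/family-holdout split construction, label-shuffling
    straw-model controls, feature-ablation combiners, the CI/MSE/rm2/AUPR
    evaluation suite, and a synthetic-data generator with planted protein
    family structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: Software, Proteomics, Cheminformatics, MachineLearning, Alignment
RoxygenNote: 7.3.3
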