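Package: phosphorelay
Title: Structural and Sequence Analytics for Histidine-Kinase Phosphorelays
Version: 0.1.0
Authors@R: person("Relay", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Toolkit for analysing intramolecular phosphotransfer in hybrid
    histidine kinases and their receiver (Rec) domain partners. Reads and
    writes PDB/mmCIF structures, performs Kabsch rigid-body superposition with
    iterative outlier pruning, builds template-grafted models of
    phosphotransfer-competent DHp/Rec complexes, analyses protein-protein
    interfaces (Shrake-Rupley solvent accessibility, buried area, crystal
    lattice contacts, salt bridges), profiles Rec-family multiple sequence
    alignments (information content, differential conservation, FxSGY motif
    scanning), scores residue covariation with average-product-corrected
    mutual information, and processes backbone NMR chemical shifts (amide
    chemical-shift perturbation, secondary shifts versus random coil with
    1-2-1 smoothing, heteronuclear NOE mobility flags, Gaussian line-width
    fitting). Ships seeded synthetic-data generators so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
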