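Package: taucore
Title: Nucleation-Core Contact Analysis and Strain Classification for Tau Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the hexameric aggregation nucleation cores of the
    microtubule-associated protein tau in fibril protomer structures. Reads fibril
    coordinates from PDB and mmCIF files, enumerates intra-protomer hydrogen-bond and
    hydrophobic contacts under distance criteria (3.3 and 5.0 Angstrom heavy-atom
    cutoffs), locates the PHF6 (VQIVYK) and PHF6* (VQIINK) nucleation motifs in
    modeled sequences, classifies tauopathy folds into single- and dual-core strains,
    reports the residue-pair interactions lost when the VYK or INK motif suffix is
    truncated, and ranks cores by interaction count. Also rebuilds the six tau
    isoforms and systematic truncation and hexamer-extension construct series from a
    domain-boundary map, applies an intact-hexamer amyloidogenicity rule, simulates
    thioflavin-T aggregation kinetics, and calls aggregation from logistic fits.
    Synthetic structure fixtures with exactly known planted contacts make every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
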