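Package: lactylKC
Title: Spatial Lysine-Cysteine Distance Analysis of Protein Lactylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for analysing nonenzymatic lysine D-lactylation in the
    light of protein structure. Computes, for every lysine in a structure or a
    whole proteome of structures, the Euclidean distance from its epsilon-amino
    nitrogen (NZ) to the spatially nearest cysteine thiol sulfur (SG) -- the
    "KC distance" -- from PDB coordinate files; normalises label-free
    modification-site intensity tables (relative values with protein-level
    correction), computes replicate fold changes with Welch tests and
    Benjamini-Hochberg adjustment, and classifies regulated sites; performs
    position-specific amino-acid enrichment around modified lysines against a
    proteome lysine background, including cysteine spacing patterns (KXC,
    CXXK, CXXXK); and compares KC-distance distributions across site classes
    and subcellular compartments with Mann-Whitney tests. A seeded synthetic
    data generator produces structures, proteomes, site tables and intensity
    matrices with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    limma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
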