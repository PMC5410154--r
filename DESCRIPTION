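Package: venomont
Title: Ontogenetic Analysis of Venom-Gland Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing ontogenetic (adult versus juvenile)
    shifts in snake venom composition from venom-gland RNA-seq data.
    Implements a greedy seed-extension transcript assembler, divergence-based
    consensus clustering of toxin paralogs with a coverage-profile chimera
    screen, coverage-based transcript presence/absence calling, a
    compositional (centered log-ratio) outlier test for adult/juvenile
    expression change calibrated against a nontoxin-derived empirical null
    with a majority-consensus rule across paired populations, and
    Spearman-Karber median lethal dose (LD50) estimation. Ships transcribed
    reference tables for the eastern diamondback rattlesnake (Crotalus
    adamanteus) and a synthetic-data generator so every stage of the pipeline
    can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
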