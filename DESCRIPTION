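Package: osteoid
Title: Biomolecular Identification of Historical Human Remains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for the biomolecular lines of evidence used to
    assess the identity of historical skeletal remains: collagen elemental
    quality control (atomic C/N ratio), dietary marine-fraction estimation by
    stable-isotope endmember mixing, radiocarbon calibration against a
    diet-weighted mixture of atmospheric and marine calibration curves with a
    local reservoir offset, ancient-DNA authentication from terminal
    deamination damage profiles, pileup-based mitochondrial consensus calling
    and haplogroup assignment against a defining-variant tree, and
    maximum-parsimony phylogenetic placement. A synthetic-data module
    generates ancient reads with parameterised damage, haplotypes from a
    haplogroup tree, calibration curves with closed-form posteriors, and
    isotope reference clusters, so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
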