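Package: auxiaa
Title: Genome-Wide Aux/IAA Gene Family Survey Toolkit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of the Aux/IAA
    auxin-repressor gene family (and similar motif-defined families):
    motif-based family identification and canonical/non-canonical degron
    classification, physicochemical profiling, chromosome distribution and
    tandem-cluster detection, protein alignment with UPGMA phylogenies and
    bootstrap support, collinearity-based duplication-mode classification
    (WGD/segmental, tandem, transposed, dispersed), Nei-Gojobori Ka/Ks
    estimation with synonymous-rate dating and whole-genome-duplication
    event binning, strand-aware promoter extraction with degenerate
    (IUPAC) cis-element scanning, and RPKM-based expression analysis with
    differential-expression and paralog expression-divergence calls. Ships
    a synthetic-data generator that builds complete, internally consistent
    fixture genomes encoding published chickpea and soybean family
    catalogs, so the whole pipeline can be exercised end to end at desk
    scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
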