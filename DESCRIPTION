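Package: scmito
Title: Mitochondrial Genome Reconstruction and Heteroplasmy Analysis for Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs mitochondrial DNA (mtDNA) consensus genomes from
    single-cell sequencing reads and characterises them: adapter/quality
    trimming, seed-and-extend alignment to the circular mitochondrial
    reference with nuclear-decoy (NumtS) filtering and PCR-duplicate removal,
    quality-filtered pileup with heteroplasmy-aware variant calling and
    contig-level consensus assembly, haplogroup classification with a
    reliability score, coverage-uniformity diagnostics (Lorenz curve, Gini
    coefficient), and cell-to-cell / cell-to-bulk variant concordance
    analytics. Ships a synthetic-data generator emulating the coverage bias,
    duplicates, sequencing error and NumtS contamination of common
    whole-genome-amplification protocols (MDA, eWGA, DOP-PCR, MALBAC), bulk
    and ATAC-like libraries, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    vcfR,
    methods,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
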