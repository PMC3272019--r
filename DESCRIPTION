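Package: mircensus
Title: Census of miRNA Variants from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the census of microRNA variants in small
    RNA sequencing libraries. Collapses reads to tags, aligns them to
    precursor hairpins and a genome with mismatch and multimapping
    resolution, applies an operational taxonomy of miRNA variants (generic
    mature/star calls, 5' and 3' isomiRs, novel miR*, extreme isomiRs,
    antisense miRNAs), quantifies hairpin arm strand bias, analyses terminal
    nucleotide composition and duplex geometry around Drosha and Dicer
    cleavage sites from dot-bracket secondary structures, discovers novel
    hairpin candidates from phased genomic tag clusters, and scans seed
    matches in 3' UTR sets. Includes a synthetic-data generator with planted
    ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
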