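Package: satchrom
Title: Satellitome Chromosomal Mapping, Quantification and Divergence Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps satellite-DNA (satDNA) consensus monomers onto a genome
    assembly with a k-mer seed-and-extend matcher (or imported BLAST tabular
    hits), merges overlapping hits into discrete loci, quantifies copy number
    and genomic abundance per chromosome, classifies families as
    chromosome-specific, multi-chromosomal or pan-chromosomal, builds Kimura
    two-parameter divergence landscapes, contrasts assembly-based with
    read-based abundance estimates to expose assembly-collapse and
    mapping-bias effects, and detects terminal and interstitial telomeric
    (TTAGGG)n arrays. Ships a synthetic-satellitome generator (planted tandem
    arrays under a Kimura substitution process, read simulation, assembly
    collapse) that emits ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
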