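Package: mitocomp
Title: Comparative Analysis of Nematode Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing circular mitochondrial genomes of
    chromadorean nematodes: circular-coordinate arithmetic and feature-table
    input/output, intergenic/overlap accounting, protein-coding gene
    verification under the invertebrate mitochondrial genetic code (including
    incomplete, polyadenylation-completed stop codons), nucleotide composition
    and codon-usage statistics, secondary-structure folding of mitochondrial
    tRNAs under the nematode TV-replacement-loop model, tandem-repeat
    discovery in non-coding control regions, gene-order adjacency and
    breakpoint comparison, and preparation of codon alignments and partitioned
    supermatrices for downstream phylogenetic inference. A fully specified
    synthetic-mitogenome generator makes every stage of the pipeline testable
    without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
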