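Package: stopscan
Title: Detection of Stop-Codon Reassignment in Nuclear Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the amino-acid meaning of candidate stop codons from
    genome assemblies, gene models and orthogroup protein alignments, using
    conserved-site codon-meaning voting, protein-to-genome alignment
    stop-context tallies, gene-body positional frequency profiles, codon
    usage statistics and suppressor-tRNA identity-element analysis. Includes
    a fully seeded synthetic-data generator that emulates genomes under
    standard and variant nuclear genetic codes (NCBI translation tables 1,
    6, 15 and 16) for validation of every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
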