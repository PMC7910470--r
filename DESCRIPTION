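Package: barcodeaudit
Title: Audit Tools for COI DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and analytics for cytochrome c oxidase subunit I
    (COI) DNA barcode reference libraries, as used when curating barcode
    collections for species identification of insects such as wild bees.
    Provides reading-frame and stop-codon screening for putative nuclear
    mitochondrial pseudogenes (numts), Kimura 2-parameter pairwise distances
    with pairwise deletion, rank-stratified divergence summaries, barcode-gap
    analysis against nearest-neighbour species, threshold single-linkage
    clustering with species-concordance classification (match, split, merge,
    mixture), per-species haplotype counts and Nei haplotype diversity,
    neighbour-joining trees with Newick export, a one-command audit pipeline,
    and a sequence simulator that generates barcode libraries with realistic
    intra- and interspecific divergence structure for testing.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
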