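Package: magqc
Title: Quality Control for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for evaluating metagenome assembly and binning when
    reconstructing population genomes from shotgun metagenomes. Computes
    contig-continuity statistics (N50, L50, reads assembled), detects contig
    chimerism through a bootstrap comparison of taxon richness and evenness
    between raw reads and assembled contigs, profiles taxonomic composition
    from kmer frequencies by non-negative least squares, scores bins by GC
    variation, genus richness and single-copy marker completeness and
    contamination, classifies bins as metagenome-assembled genomes,
    potentially novel genomes, or mixed bins, and measures genome relatedness
    by fragment-based average nucleotide identity and tetranucleotide z-score
    correlation. A seeded community simulator generates genomes, reads,
    contigs (with chimera injection), bins and reference signatures so the
    whole workflow is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
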