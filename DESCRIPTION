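Package: gtacarbon
Title: Energetic Cost and Codon-Position GC Analysis of Gene Transfer Agent Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the energetic economics of bacterial gene transfer
    agent (GTA) gene clusters. Decomposes GC content by codon position for
    gene regions, their flanking neighborhoods and whole genomes; scores
    proteins by side-chain carbon content and amino-acid biosynthetic cost
    (high-energy phosphate bonds); normalizes carbon utilization by
    single-copy housekeeping genes; dereplicates genome sets by
    complete-linkage clustering of average nucleotide identity; reconstructs
    ancestral states of a continuous carbon-utilization trait under Brownian
    motion and ancestral protein sequences under an empirical amino-acid
    model with Gamma rate heterogeneity; and tests for net carbon-content
    change on branches leading to viral homologs with an alignment-column
    bootstrap. Includes a synthetic-data generator that emulates the
    statistical structure of GTA-bearing genomes and protein families so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
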