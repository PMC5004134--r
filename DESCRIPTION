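Package: hybridolc
Title: Hybrid Overlap-Layout-Consensus Assembly of Long Erroneous Reads
    Anchored on Accurate Short-Read Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles long, high-error sequencing reads (PacBio/Nanopore
    class, 15-40 percent error) by compressing each read into an ordered,
    oriented list of short-read contig identifiers via a unique k-mer index,
    computing identifier-level Smith-Waterman overlaps in the compressed
    domain, removing spurious anchors and splitting chimeric reads with a
    multiple-alignment pileup, building and simplifying a best overlap
    graph, laying linear paths out into draft backbones (patching long-read
    coverage gaps with contig sequence), and polishing each backbone with a
    sparse k-mer graph consensus whose heaviest path is the final sequence.
    Includes a ground-truth simulator for genomes, contigs and erroneous
    long reads so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
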