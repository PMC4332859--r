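Package: edittags
Title: Design of Edit-Distance DNA Tag Sets with a Greedy-Closure Genetic Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs sets of DNA sequence tags (multiplexing barcodes) whose
    pairwise Levenshtein edit distances, GC content, homopolymer run lengths
    and complementarity relations satisfy configurable thresholds. The core
    designer is a modified genetic algorithm with greedy closure: a population
    evolves over the 4^n sequence space and every individual whose tag-tag
    edit distance to the growing result set reaches the minimum distance d is
    appended to that set. Also provides a fixed-count GC constraint that pins
    every tag to exactly floor(n/2) G/C bases, a cross-tag reverse-complement
    exclusion rule, a greedy lexicode baseline, an exact branch-and-bound
    optimum for tiny instances, nearest-neighbor melting-temperature
    evaluation with the Tm-gap set quality metric, and FASTA/TSV input and
    output for tag sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
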