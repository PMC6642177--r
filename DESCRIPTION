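Package: svbench
Title: Structural Variant Benchmarking Against Simulated Truth Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for benchmarking structural variant (SV) callers against
    truth sets. Converts VCF call sets (symbolic SV alleles and BND breakend
    notation) to breakpoint calls, matches them to truth breakpoints under a
    positional window with micro-homology ambiguity intervals and a relative
    size tolerance, and derives precision, recall and quality-threshold
    curves. Includes an SV genome simulator (deletions, insertions,
    inversions, tandem duplications and intra-chromosomal translocations)
    emitting rearranged haplotypes with truth VCFs and error-free paired
    reads, genomic-context stratification (repeat class, tandem repeats,
    blacklists, high-confidence regions, nearby small variants), exhaustive
    m-of-n ensemble evaluation with divided totals, and quality-score bin
    diagnostics with exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
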