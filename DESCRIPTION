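Package: methylscan
Title: Downstream Analysis of Whole-Genome Bisulfite Sequencing Methylation Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Context-stratified DNA methylation analysis on per-cytosine call
    files in the CGmap dialect: coverage filtering, per-site / per-region /
    per-sample / per-group methylation levels, metagene profiles over gene
    bodies and 15 kb flanks, repeat-element and genic-partition methylation,
    CG-density-based promoter classification (HCG/ICG/LCG), and sliding-window
    differential-methylation-region (DMR) screening with interval-based gene
    annotation. Includes a deterministic synthetic-study generator (toy genome,
    gene and repeat annotations, replicate call files with planted DMRs) so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
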