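Package: parscope
Title: Sex-Chromosome Sequence Architecture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed exact-match dot plots, collinear X-Y identity profiling
    and pseudoautosomal-boundary detection, ampliconic and tandem-array
    calling, five-class sequence segmentation, GC-elevation statistics, Hi-C
    flank-link contig ordering, and male/female k-mer ("electronic")
    subtraction, together with a synthetic X/Y genome generator reproducing
    the sequence architecture of a recently assembled mammalian Y chromosome
    so every analysis can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
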