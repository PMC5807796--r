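Package: lrbridge
Title: Hybrid Long-Read Error Correction with an FM-Index over Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Corrects high-error long sequencing reads using an accurate
    short-read dataset indexed by a multi-string Burrows-Wheeler transform.
    The FM-index over the short reads acts as an implicit, dynamically
    pruned de Bruijn graph at every k-mer size simultaneously; long reads
    are corrected in two passes (a short k-mer pass and a long K-mer pass)
    by replacing weak regions with graph paths anchored at solid k-mers,
    selecting among candidate paths by edit distance.  Includes a
    truth-tracking read simulator and a per-locus evaluation module
    reporting sensitivity, specificity and gain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
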