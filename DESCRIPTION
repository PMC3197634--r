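Package: msvscan
Title: Accelerated Profile HMM Homology Search with an MSV Filter Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profile hidden Markov model protein homology search built around
    a staged acceleration pipeline. Implements the multiple segment Viterbi
    (MSV) multihit ungapped filter in both full floating-point precision and
    a striped, saturated 8-bit integer form; a striped 16-bit Viterbi filter
    for gapped optimal alignment; Forward/Backward ensemble scoring with a
    log-sum reference implementation and an odds-ratio-domain sparse-rescaling
    parser with endpoint posterior decoding; Gumbel and exponential-tail
    E-value statistics with simulation-based calibration; a benchmark
    constructor for sensitivity/specificity evaluation (clustered query
    alignments, embedded true-test domains, matched decoys); and readers and
    writers for FASTA, Stockholm, and a documented text profile format.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
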