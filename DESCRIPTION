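Package: cqs
Title: Codebook-Based Lossless Compression of FASTQ Quality Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lossless, reference-free compression of the quality-score lines
    of FASTQ files. Quality sequences are Huffman-coded and repacked into
    6-bit printable ASCII, a codebook of code vectors is designed by a
    memetic algorithm (self-adaptive differential evolution with fitness
    sharing for multimodal search, plus a derivative-free line-search
    refinement), and each read is stored as a code-vector index together
    with a minimal-bit-cost edit script obtained by dynamic programming.
    Includes the exact decoder, a self-contained container format, a
    seeded synthetic FASTQ generator for testing, and compression metrics
    (compression ratio and bits per quality value).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
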