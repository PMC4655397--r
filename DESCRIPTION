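Package: triodiff
Title: Replicate-Free Differential Expression Across Three Tissue Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing transcript expression among three tissue
    libraries sequenced without biological replication, as is common when a
    transcriptome database is assembled from pooled specimens. Provides FPKM
    quantification from transcript-level read counts, parts-per-million
    abundance filtering, empirical mean +/- 2 SD log2-ratio differential
    expression calls, tissue-dominance classification, selection of the top
    fraction of transcripts by total expression, cumulative hypergeometric
    term over-representation tests with rich factors, relative quantification
    of qPCR Ct tables by the 2^-ddCt method with concordance scoring against
    sequencing-based ratios, transcriptome assembly summary statistics and
    Cys-Xaa-Cys motif scanning, and a seeded synthetic-data generator with
    known tissue-dominant ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
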