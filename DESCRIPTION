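Package: codonreuse
Title: Synonymous Codon Pair Co-Occurrence and tRNA Reuse Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-scale analysis of consecutive synonymous codon usage
    (co-tRNA codon pairing bias). Extracts coding sequences from GenBank
    flat files or CDS FASTA, partitions the genetic code into synonymous
    codon families with tRNA isoacceptor (wobble) groupings, counts
    ordered codon-pair co-occurrences per family under several pairing
    strategies, and scores each pair against a positional-independence
    expectation with three deviation statistics (percent deviation,
    binomial z, log2 observed/expected ratio) plus a Monte-Carlo
    empirical-null quantile. Includes a synthetic-genome generator with
    a controllable first-order codon-reuse parameter for calibration and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
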