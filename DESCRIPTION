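Package: itrseek
Title: Insertion Sequence Discovery from Mixed-Community Short Reads via
    Inverted Terminal Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers insertion sequences (IS) in short reads sequenced
    from mixed microbial communities. Inter-read repeats are found with a
    maximal-exact-match search over a 2-bit packed read store using a
    sparse k-mer index, projected onto assembly contigs, paired as
    candidate inverted terminal repeats (ITRs) by proximity, validated by
    greedy identity clustering plus reverse-complement alignment, filtered
    on transposase annotation, and emitted as a named, dereplicated IS
    catalogue. Includes a synthetic-data generator that plants ISs with
    known coordinates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
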