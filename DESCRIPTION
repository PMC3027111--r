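Package: proteolm
Title: N-Gram Language Models and Composition Signatures for Whole Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free comparison of whole proteomes through amino-acid
    n-gram statistics: n-gram counting with configurable alphabet policies,
    comparative Zipf-like rank-frequency profiling and signature extraction,
    count-ratio n-gram language models with self- and cross-perplexity,
    top-k frequency correlation summaries by genus, and unigram-based
    taxonomic classification with multinomial logistic regression. Includes
    a hierarchical Markov-chain proteome simulator with a known taxonomy and
    known divergence structure so every stage can be exercised end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
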