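Package: kmerscreen
Title: Foreign Vector DNA Screening in Resequenced Genomes by Exact k-mer Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unintended remnants of vector (plasmid) DNA in a
    whole-genome resequencing sample without a reference genome. Reads are
    decomposed into k-mers on both strands and matched exactly against a
    (possibly circular) vector sequence; per-position match counts are
    compared between the test sample and a wild-type contrast with a
    one-sided G-test of independence, and an insert is called detected when
    at least one vector position inside the insert's source interval is
    significant. Includes a paired-end short-read simulator with
    substitution errors, Monte-Carlo power and coverage-sweep campaigns,
    and k-mer pattern-uniqueness census utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    withr,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
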