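Package: l1rescue
Title: Treatment-Rescue Analysis of Gene and LINE-1 Expression in Trisomic Mouse Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq count data from a 2x2
    genotype-by-treatment mouse study design with pooled samples:
    negative-binomial Wald differential expression with median-of-ratios
    normalisation and Benjamini-Hochberg adjustment, a treatment-rescue set
    criterion applicable to genes and LINE-1 retrotransposon loci, LINE-1
    transcript-fraction and nearest-gene summaries, novel-object-recognition
    discrimination-index analysis with learner classification and
    expression-behaviour correlation, hypergeometric over-representation
    against user-supplied gene sets, and a negative-binomial count simulator
    that emulates the study design with recorded ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
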