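Package: reosig
Title: Rank-Based Gene-Pair Prognostic Signatures from Relative Expression Orderings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery, validation and application of gene-pair prognostic
    signatures built on within-sample relative expression orderings (REOs).
    Implements differential-expression screening, Fisher-exact reversal
    screening of gene pairs with Benjamini-Hochberg FDR control,
    cross-dataset consistency filtering, univariate Cox filtering and
    greedy forward selection under a majority-vote classification rule,
    together with the survival machinery (Kaplan-Meier, log-rank, Cox
    proportional hazards, Harrell's C-index), binomial concordance scores,
    hypergeometric overlap and gene-set enrichment statistics, and a
    synthetic-cohort generator with planted reversed gene pairs and
    censored relapse-free survival for fully offline verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
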