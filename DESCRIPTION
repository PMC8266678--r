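Package: reodiff
Title: Individualized Differential Expression of lncRNAs from Relative
    Expression Orderings
Version: 0.1.0
Authors@R:
    person("reodiff", "maintainers", email = "reodiff@example.org",
           role = c("aut", "cre"))
Description: Calls per-tumor-sample up/down/unaltered status for long
    non-coding RNAs by comparing within-sample expression orderings
    against gene pairs whose ordering is stable across a normal
    reference cohort (a rank-reversal Fisher exact test in the
    RankComp lineage). Includes paired-sample cross-validation of
    call accuracy, consistency scoring against copy-number and
    promoter-methylation alterations, subtype over-representation and
    lncRNA-gene co-occurrence networks, prognostic selection and
    two-class hierarchical clustering of ternary alteration profiles
    with log-rank comparison, drug-response association, a
    ground-truth synthetic data generator, and an end-to-end pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
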