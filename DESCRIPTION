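Package: consensusDEG
Title: Consensus Differential Expression and Twin-Discordance Analysis for
    Whole-Blood RNA-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for transcript-level biomarker discovery
    from whole-blood RNA-seq count matrices in two-cohort designs: an unpaired
    case-control cohort and a cohort of discordant monozygotic twin pairs.
    Provides a battery of differential-expression statistics (negative-binomial
    exact test, negative-binomial likelihood-ratio and Wald generalized linear
    models, empirical-Bayes moderated t on log-CPM, and a Dirichlet Monte-Carlo
    centered-log-ratio test) over TMM, median-of-ratios and iterative
    DEG-elimination (DEGES) normalizations; appearance-count consensus ranking
    of per-method top-K lists; RPKM prevalence filtering and a joint
    fold-change / p-value / expression triple filter; cross-cohort symbol
    intersection with direction concordance and a hypergeometric overlap test;
    and correlation of within-pair expression fold changes with ADHD rating
    scale discrepancy ranks. A negative-binomial synthetic-cohort generator
    with known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    DESeq2,
    optparse
Config/testthat/edition: 3
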