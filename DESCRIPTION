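Package: zeroinone
Title: Benchmarking Differential Expression Methods for Genes Expressed in
    Only One Condition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how RNA-seq differential-expression methods behave
    for genes whose counts are zero in every replicate of one condition.
    Provides the per-gene signal-to-noise statistic computed from the non-zero
    condition on linear counts-per-million, log counts-per-million and a
    variance-stabilized scale, together with the theoretical negative-binomial
    signal-to-noise curve; a negative-binomial simulator that injects all-zero
    conditions into a null count table as ground-truth differential expression;
    transparent surrogate tests for the count-based (conditional exact
    negative-binomial) and transform-based (precision-weighted moderated t)
    method families plus an adapter for externally computed results; and
    percentile-label ROC and achieved-FDR evaluation of the resulting rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    optparse,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma
Config/testthat/edition: 3
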