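Package: dnamclock
Title: Elastic-Net DNA Methylation Clocks, Rejuvenation Statistics, and
    Epigenome-Wide Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds DNA-methylation age estimators ("epigenetic clocks") by
    elastic-net penalized regression of chronological age (or relative age,
    age divided by species maximum lifespan) on CpG beta values, with an
    in-package cyclic coordinate-descent solver, internal 10-fold
    cross-validation for the penalty, and leave-one-out or k-fold external
    cross-validation reporting the age correlation R and the median absolute
    error. Includes group-level treatment statistics (rejuvenation
    percentage, one-way ANOVA, Student's t, Kruskal-Wallis), a per-CpG
    epigenome-wide association stage with unwanted-variation factors,
    empirical-Bayes moderated t-statistics and Benjamini-Hochberg correction,
    a synthetic multi-tissue dual-species methylome generator with known
    aging structure for end-to-end validation, and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
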