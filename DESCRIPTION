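Package: hospeff
Title: Two-Stage Bootstrap Data Envelopment Analysis for Health-Facility
    Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Output-oriented data envelopment analysis (CCR, BCC and
    non-increasing returns-to-scale envelopment linear programs) with
    Simar-Wilson smoothed homogeneous bootstrap bias correction of
    technical, pure technical and scale efficiency scores, and bootstrap
    truncated-normal regression (Simar-Wilson algorithm 2) of
    bias-corrected scores on environmental covariates.  Includes a
    synthetic generator of hospital-like decision-making-unit panels with
    a known Cobb-Douglas frontier and known covariate-driven
    inefficiency, a variable-screening funnel (hierarchical clustering,
    correlation pruning and an R-squared screen), pooled-variance group
    comparisons, score-band summaries and an end-to-end reporting
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
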