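Package: phecad
Title: Portable Electronic Medical Record Phenotyping of Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating a portable electronic medical
    record (EMR) phenotype algorithm for coronary artery disease (CAD) that
    transfers across disease cohorts with very different CAD prevalence
    (diabetes mellitus, inflammatory bowel disease, rheumatoid arthritis).
    Implements the two-stage classification procedure: a high negative
    predictive value rule-based screen on ICD9 codes and NLP concept mentions,
    followed by an adaptive-LASSO penalized logistic phenotype model with BIC
    penalty selection and per-cohort probability cutoffs anchored to a common
    target positive predictive value. Includes a seeded synthetic multi-cohort
    EMR generator with known ground truth, two-by-two performance evaluation,
    structured-only versus structured-plus-NLP comparison, and the downstream
    cross-cohort CAD risk comparison (unadjusted odds ratios with Woolf
    confidence intervals and covariate-adjusted logistic regression).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
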