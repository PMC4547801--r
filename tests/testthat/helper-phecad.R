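# Shared fixtures and independent oracles for the test suite.

# One-or-more hand-built patient records with all evidence zeroed unless
# overridden.
make_records <- function(n = 1, ...) {
  base <- data.frame(
    patient_id = sprintf("T-%03d", seq_len(n)),
    cohort = "RA",
    age = 60, sex = "F", race = "white",
    htn = 0L, hyperlipidemia = 0L, ever_smoker = 0L,
    followup_months = 96,
    icd9_410.9 = 0L, icd9_411.1 = 0L, icd9_412 = 0L,
    icd9_413.9 = 0L, icd9_414.01 = 0L, icd9_414.8 = 0L,
    cpt_cabg = 0L, cpt_pci = 0L, cpt_stress_test = 0L,
    cpt_echocardiogram = 0L,
    total_fact_count = 40L,
    nlp_cad = 0L, nlp_cad_procedure = 0L, nlp_cad_biomarker = 0L,
    nlp_positive_stress = 0L, nlp_never_smoker = 0L,
    nlp_current_smoker = 0L,
    ldl_values = "110.5;98.2",
    true_cad = 0L, reviewed_label = NA_integer_,
    stringsAsFactors = FALSE, check.names = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# A feature_matrix wrapper around an already-standardized numeric matrix,
# for exercising the penalized fitter directly.
make_feature_matrix <- function(z, feature_set = "structured_plus_nlp") {
  if (is.null(colnames(z))) colnames(z) <- paste0("x", seq_len(ncol(z)))
  nm <- colnames(z)
  structure(list(
    x = z, feature_names = nm,
    provenance = stats::setNames(rep("structured", length(nm)), nm),
    standardization = list(center = stats::setNames(rep(0, length(nm)), nm),
                           scale = stats::setNames(rep(1, length(nm)), nm),
                           ldl_fill = 0, feature_set = feature_set,
                           dropped = character(0))),
    class = "feature_matrix")
}

# Independent Newton-Raphson logistic MLE (oracle for the unpenalized limit
# of the adaptive-LASSO path). Deliberately written against the raw score
# equations, not shared with any package code.
oracle_logistic_mle <- function(x, y, tol = 1e-12, max_iter = 100) {
  xa <- cbind(1, x)
  b <- rep(0, ncol(xa))
  for (i in seq_len(max_iter)) {
    eta <- drop(xa %*% b)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(xa, y - p))
    h <- crossprod(xa * (p * (1 - p)), xa)
    b <- b + solve(h, g)
    if (max(abs(g)) < tol) break
  }
  b
}

# Exhaustive threshold-calibration oracle: tabulate PPV and sensitivity at
# every observed probability, keep the qualifying cutoffs, and return the one
# with maximal sensitivity (ties broken to the smallest cutoff).
oracle_calibrate <- function(p, y, target) {
  cand <- sort(unique(p))
  tab <- do.call(rbind, lapply(cand, function(cc) {
    cls <- p >= cc
    data.frame(cutoff = cc, ppv = sum(y[cls]) / sum(cls),
               sens = if (sum(y) > 0) sum(y[cls]) / sum(y) else NA_real_)
  }))
  ok <- tab[tab$ppv >= target, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  ok <- ok[order(-ok$sens, ok$cutoff), , drop = FALSE]
  ok$cutoff[1]
}

# A small ready-made cohort shared by several test files (generated once per
# test run; everything is seeded).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- default_cohort_specs(scale = 0.1)$RA
      rec <- generate_cohort(spec, seed = 424242)
      sr <- apply_screen(rec)
      rec$possible_cad <- sr$possible_cad
      rec <- sample_chart_review(rec, list(type = "screen_positive_all"))
      cache <<- rec
    }
    cache
  }
})
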