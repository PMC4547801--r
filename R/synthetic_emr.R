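#' Construct a synthetic cohort specification
#'
#' A `cohort_spec` bundles everything the synthetic EMR generator needs for one
#' disease cohort: its size, target marginal CAD prevalence, covariate
#' marginals (age, sex, race, hypertension, hyperlipidemia, smoking,
#' follow-up), per-feature emission parameters conditional on true CAD status,
#' and the true log-odds coefficients linking covariates to CAD (which induce
#' the confounding structure the downstream adjusted analysis must undo).
#'
#' @param name Cohort label, e.g. `"DM"`, `"IBD"`, `"RA"`.
#' @param n_patients Positive integer number of patients.
#' @param cad_prevalence Target marginal CAD prevalence, strictly in (0, 1).
#' @param covariate_marginals Named list with elements `age_mean`, `age_sd`,
#'   `p_female`, `p_white`, `p_black`, `p_htn`, `p_hyperlipidemia`,
#'   `p_ever_smoker`, `followup_mean_yrs`, `followup_sd_yrs`.
#' @param signal_params Named list of CAD-conditional emission parameters; see
#'   [default_signal_params()]. For every CAD-indicative feature the
#'   CAD-conditional rate must be at least the non-CAD rate.
#' @param risk_coefficients Named numeric vector of true log-odds coefficients
#'   on `age` (per year), `male`, `htn`, `hyperlipidemia`, `ever_smoker`.
#' @param cohort_log_or True cohort-level log-odds offset relative to the
#'   reference cohort, used only by [generate_pooled_cohorts()].
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [default_cohort_specs()], [generate_cohort()]
#' @export
cohort_spec <- function(name, n_patients, cad_prevalence,
                        covariate_marginals,
                        signal_params = default_signal_params(),
                        risk_coefficients = default_risk_coefficients(),
                        cohort_log_or = 0) {
  spec <- structure(
    list(name = name, n_patients = n_patients, cad_prevalence = cad_prevalence,
         covariate_marginals = covariate_marginals,
         signal_params = signal_params,
         risk_coefficients = risk_coefficients,
         cohort_log_or = cohort_log_or),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default true risk coefficients for the synthetic generator
#'
#' Log-odds coefficients linking the demographic/comorbidity covariates to
#' true CAD status. Defaults correspond to adjusted odds ratios of 1.05 per
#' year of age, 2.27 for male sex, 1.80 for hypertension, 2.48 for
#' hyperlipidemia and 1.92 for ever-smoking -- the magnitudes a large EMR
#' cohort study of CAD risk factors reports.
#'
#' @return Named numeric vector of log odds ratios.
#' @export
default_risk_coefficients <- function() {
  c(age = log(1.05), male = log(2.27), htn = log(1.80),
    hyperlipidemia = log(2.48), ever_smoker = log(1.92))
}

#' Default CAD-conditional emission parameters
#'
#' Emission model for the observable EMR features given true CAD status:
#' Poisson rates for ICD9 code counts (per code, CAD vs non-CAD), Bernoulli
#' probabilities for CPT procedure flags and NLP concept mentions
#' (sensitivity-like under CAD, one minus specificity under non-CAD),
#' smoking-mention probabilities conditional on the ever-smoker covariate,
#' a Gaussian LDL model with per-patient missingness, and a background coded
#' fact rate that drives the total fact count. NLP mention probabilities are
#' chosen so narrative data add sensitivity over structured data at matched
#' PPV, the behaviour the two-stage algorithm is designed to exploit in
#' low-prevalence cohorts.
#'
#' @return Named list of emission parameters; all rates and probabilities are
#'   per patient over their EMR history.
#' @export
default_signal_params <- function() {
  list(
    icd9_rates = data.frame(
      code = c("410.9", "411.1", "412", "413.9", "414.01", "414.8"),
      rate_cad = c(0.5, 0.3, 0.2, 0.3, 1.8, 0.2),
      rate_noncad = c(0.010, 0.006, 0.004, 0.012, 0.040, 0.006),
      stringsAsFactors = FALSE),
    cpt = list(cabg = c(cad = 0.18, noncad = 0.001),
               pci = c(cad = 0.22, noncad = 0.002),
               stress_test = c(cad = 0.40, noncad = 0.08),
               echocardiogram = c(cad = 0.55, noncad = 0.25)),
    nlp = list(cad = c(cad = 0.92, noncad = 0.05),
               cad_procedure = c(cad = 0.45, noncad = 0.010),
               cad_biomarker = c(cad = 0.30, noncad = 0.020),
               positive_stress = c(cad = 0.35, noncad = 0.012)),
    nlp_smoking = c(p_never_given_never = 0.80, p_never_given_ever = 0.05,
                    p_current_given_ever = 0.40, p_current_given_never = 0.02),
    ldl = c(p_missing = 0.15, n_mean = 3,
            mean_cad = 100, mean_noncad = 112, sd = 28),
    background_facts = c(rate_per_year = 6, extra_cad = 10)
  )
}

#' Validate a cohort specification
#'
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_cohort_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort_spec field '%s': %s", field, why), call. = FALSE)
  }
  if (!is.character(spec$name) || length(spec$name) != 1L || !nzchar(spec$name))
    fail("name", "must be a non-empty string")
  if (!is.numeric(spec$n_patients) || length(spec$n_patients) != 1L ||
      spec$n_patients < 1 || spec$n_patients != round(spec$n_patients))
    fail("n_patients", "must be a positive integer")
  p <- spec$cad_prevalence
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    fail("cad_prevalence", "must lie strictly in (0, 1)")
  cm <- spec$covariate_marginals
  need <- c("age_mean", "age_sd", "p_female", "p_white", "p_black", "p_htn",
            "p_hyperlipidemia", "p_ever_smoker", "followup_mean_yrs",
            "followup_sd_yrs")
  miss <- setdiff(need, names(cm))
  if (length(miss))
    fail("covariate_marginals", paste("missing:", paste(miss, collapse = ", ")))
  probs <- cm[c("p_female", "p_white", "p_black", "p_htn", "p_hyperlipidemia",
                "p_ever_smoker")]
  if (any(vapply(probs, function(x) x < 0 || x > 1, logical(1))))
    fail("covariate_marginals", "probabilities must lie in [0, 1]")
  if (cm$p_white + cm$p_black > 1)
    fail("covariate_marginals", "p_white + p_black must not exceed 1")
  if (cm$age_sd <= 0 || cm$followup_sd_yrs <= 0)
    fail("covariate_marginals", "standard deviations must be positive")
  sp <- spec$signal_params
  if (any(sp$icd9_rates$rate_cad < 0) || any(sp$icd9_rates$rate_noncad < 0))
    fail("signal_params", "Poisson rates must be nonnegative")
  if (any(sp$icd9_rates$rate_cad < sp$icd9_rates$rate_noncad))
    fail("signal_params",
         "CAD-conditional ICD9 rate below the non-CAD rate for a CAD-indicative code")
  for (nm in names(sp$cpt)) {
    pr <- sp$cpt[[nm]]
    if (any(pr < 0) || any(pr > 1)) fail("signal_params", paste0("cpt$", nm, " outside [0, 1]"))
    if (pr["cad"] < pr["noncad"])
      fail("signal_params", paste0("cpt$", nm, ": CAD-conditional probability below non-CAD"))
  }
  for (nm in names(sp$nlp)) {
    pr <- sp$nlp[[nm]]
    if (any(pr < 0) || any(pr > 1)) fail("signal_params", paste0("nlp$", nm, " outside [0, 1]"))
    if (pr["cad"] < pr["noncad"])
      fail("signal_params", paste0("nlp$", nm, ": CAD-conditional probability below non-CAD"))
  }
  if (sp$ldl["p_missing"] < 0 || sp$ldl["p_missing"] > 1)
    fail("signal_params", "ldl p_missing outside [0, 1]")
  rc <- spec$risk_coefficients
  need_rc <- c("age", "male", "htn", "hyperlipidemia", "ever_smoker")
  if (!all(need_rc %in% names(rc)))
    fail("risk_coefficients",
         paste("missing:", paste(setdiff(need_rc, names(rc)), collapse = ", ")))
  invisible(spec)
}

#' Default RA / IBD / DM cohort specifications
#'
#' Cohort sizes, CAD prevalences and covariate marginals matching the three
#' EMR disease cohorts the two-stage algorithm was designed for: rheumatoid
#' arthritis (n = 4,453, prevalence 5.0%), inflammatory bowel disease
#' (n = 10,974, 4.2%) and diabetes mellitus (n = 65,099, 26.1%). Cohort-level
#' true log odds ratios (vs DM) default to log(0.37) for RA and log(0.34) for
#' IBD and are used only by the pooled generator.
#'
#' @param scale Multiplier on cohort sizes (e.g. `scale = 0.1` for a tenth of
#'   the full sizes); sizes are rounded and floored at 50.
#' @return Named list of three [cohort_spec()] objects (`RA`, `IBD`, `DM`).
#' @export
default_cohort_specs <- function(scale = 1) {
  stopifnot(is.numeric(scale), scale > 0)
  n <- function(n0) max(50L, as.integer(round(n0 * scale)))
  list(
    RA = cohort_spec(
      name = "RA", n_patients = n(4453), cad_prevalence = 0.05,
      covariate_marginals = list(
        age_mean = 60.9, age_sd = 14.8, p_female = 0.791,
        p_white = 0.669, p_black = 0.057, p_htn = 0.384,
        p_hyperlipidemia = 0.291, p_ever_smoker = 0.485,
        followup_mean_yrs = 8.6, followup_sd_yrs = 5.5),
      cohort_log_or = log(0.37)),
    IBD = cohort_spec(
      name = "IBD", n_patients = n(10974), cad_prevalence = 0.042,
      covariate_marginals = list(
        age_mean = 47.3, age_sd = 18.8, p_female = 0.532,
        p_white = 0.853, p_black = 0.030, p_htn = 0.257,
        p_hyperlipidemia = 0.231, p_ever_smoker = 0.590,
        followup_mean_yrs = 7.1, followup_sd_yrs = 5.7),
      cohort_log_or = log(0.34)),
    DM = cohort_spec(
      name = "DM", n_patients = n(65099), cad_prevalence = 0.261,
      covariate_marginals = list(
        age_mean = 64.6, age_sd = 15.4, p_female = 0.469,
        p_white = 0.672, p_black = 0.121, p_htn = 0.806,
        p_hyperlipidemia = 0.680, p_ever_smoker = 0.732,
        followup_mean_yrs = 8.1, followup_sd_yrs = 5.9),
      cohort_log_or = 0)
  )
}

# Draw the covariate block for n patients from the spec's marginals.
# Covariates are mutually independent; all dependence among observable
# features is induced downstream through true CAD status.
draw_covariates <- function(spec, n) {
  cm <- spec$covariate_marginals
  age <- pmin(pmax(rnorm(n, cm$age_mean, cm$age_sd), 18), 100)
  sex <- ifelse(runif(n) < cm$p_female, "F", "M")
  u <- runif(n)
  race <- ifelse(u < cm$p_white, "white",
                 ifelse(u < cm$p_white + cm$p_black, "black", "other"))
  fu_yrs <- pmin(pmax(rnorm(n, cm$followup_mean_yrs, cm$followup_sd_yrs), 0.25), 30)
  data.frame(
    age = age, sex = sex, race = race,
    htn = rbinom(n, 1, cm$p_htn),
    hyperlipidemia = rbinom(n, 1, cm$p_hyperlipidemia),
    ever_smoker = rbinom(n, 1, cm$p_ever_smoker),
    followup_months = round(fu_yrs * 12, 1),
    stringsAsFactors = FALSE)
}

# Covariate linear predictor (excluding intercept) under the spec's true
# risk coefficients.
risk_linear_predictor <- function(cov, rc) {
  rc["age"] * cov$age + rc["male"] * (cov$sex == "M") + rc["htn"] * cov$htn +
    rc["hyperlipidemia"] * cov$hyperlipidemia + rc["ever_smoker"] * cov$ever_smoker
}

# Root-find the intercept alpha so that mean(plogis(alpha + lp)) hits the
# target prevalence over the realized covariate sample.
solve_intercept <- function(lp, target) {
  uniroot(function(a) mean(plogis(a + lp)) - target,
          lower = -60, upper = 30, tol = 1e-10)$root
}

# Emit the observable EMR features conditional on true CAD status.
emit_features <- function(spec, cov, true_cad) {
  sp <- spec$signal_params
  n <- length(true_cad)
  out <- cov
  cad_code_total <- integer(n)
  for (i in seq_len(nrow(sp$icd9_rates))) {
    code <- sp$icd9_rates$code[i]
    lam <- ifelse(true_cad == 1, sp$icd9_rates$rate_cad[i], sp$icd9_rates$rate_noncad[i])
    cnt <- rpois(n, lam)
    out[[paste0("icd9_", code)]] <- cnt
    cad_code_total <- cad_code_total + cnt
  }
  for (nm in names(sp$cpt)) {
    pr <- ifelse(true_cad == 1, sp$cpt[[nm]]["cad"], sp$cpt[[nm]]["noncad"])
    out[[paste0("cpt_", nm)]] <- rbinom(n, 1, pr)
  }
  bg <- sp$background_facts
  background <- rpois(n, bg["rate_per_year"] * cov$followup_months / 12 +
                        bg["extra_cad"] * (true_cad == 1))
  out$total_fact_count <- cad_code_total + background
  for (nm in names(sp$nlp)) {
    pr <- ifelse(true_cad == 1, sp$nlp[[nm]]["cad"], sp$nlp[[nm]]["noncad"])
    out[[paste0("nlp_", nm)]] <- rbinom(n, 1, pr)
  }
  sm <- sp$nlp_smoking
  out$nlp_never_smoker <- rbinom(n, 1, ifelse(cov$ever_smoker == 1,
                                              sm["p_never_given_ever"],
                                              sm["p_never_given_never"]))
  out$nlp_current_smoker <- rbinom(n, 1, ifelse(cov$ever_smoker == 1,
                                                sm["p_current_given_ever"],
                                                sm["p_current_given_never"]))
  ld <- sp$ldl
  has_ldl <- rbinom(n, 1, 1 - ld["p_missing"]) == 1
  n_vals <- ifelse(has_ldl, 1 + rpois(n, max(ld["n_mean"] - 1, 0)), 0)
  mu <- ifelse(true_cad == 1, ld["mean_cad"], ld["mean_noncad"])
  out$ldl_values <- vapply(seq_len(n), function(i) {
    if (n_vals[i] == 0) return("")
    paste(round(rnorm(n_vals[i], mu[i], ld["sd"]), 1), collapse = ";")
  }, character(1))
  out
}

#' Generate one synthetic EMR cohort
#'
#' Draws `spec$n_patients` synthetic patients: independent covariates from the
#' spec's marginals, true CAD status from a logistic risk model on
#' age/sex/HTN/hyperlipidemia/smoking whose intercept is root-found so the
#' marginal prevalence matches `spec$cad_prevalence` over the realized
#' covariates, and then the observable structured and NLP features emitted
#' conditional on true status. Identical `(spec, seed)` pairs produce
#' byte-identical output; the caller's RNG state is untouched.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for this generation call.
#' @param intercept Optional fixed intercept on the log-odds scale; when
#'   supplied (as by [generate_pooled_cohorts()]) no prevalence root-finding is
#'   done and the marginal prevalence is whatever the intercept implies.
#' @return A data.frame with one row per patient: `patient_id`, `cohort`,
#'   demographics and comorbidities, `icd9_<code>` count columns,
#'   `cpt_*` 0/1 flags, `total_fact_count`, `nlp_*` 0/1 flags, `ldl_values`
#'   (semicolon-separated mg/dL values, `""` when none), `followup_months`,
#'   the hidden ground truth `true_cad`, and `reviewed_label` (all `NA` until
#'   [sample_chart_review()] fills it). The realized intercept is stored in
#'   `attr(, "intercept")`.
#' @export
generate_cohort <- function(spec, seed, intercept = NULL) {
  validate_cohort_spec(spec)
  with_local_seed(seed, {
    n <- spec$n_patients
    cov <- draw_covariates(spec, n)
    lp <- risk_linear_predictor(cov, spec$risk_coefficients)
    alpha <- if (is.null(intercept)) solve_intercept(lp, spec$cad_prevalence) else intercept
    true_cad <- rbinom(n, 1, plogis(alpha + lp))
    out <- emit_features(spec, cov, true_cad)
    out <- cbind(
      data.frame(patient_id = sprintf("%s-%06d", spec$name, seq_len(n)),
                 cohort = spec$name, stringsAsFactors = FALSE),
      out)
    out$true_cad <- true_cad
    out$reviewed_label <- NA_integer_
    attr(out, "intercept") <- alpha
    out
  })
}

#' Generate pooled cohorts with an exactly known cohort effect
#'
#' Generates every cohort in `specs` under a shared risk model in which the
#' cohort-level effect is an explicit parameter: the reference cohort's
#' intercept is root-found to hit its own target prevalence, and each other
#' cohort's intercept is the reference intercept plus its `cohort_log_or`.
#' The true adjusted log odds ratio of each cohort versus the reference is
#' then known exactly, which is what a parameter-recovery study of the
#' adjusted cross-cohort comparison needs. Non-reference marginal prevalences
#' are implied by the offsets rather than matched to their spec values.
#'
#' @param specs Named list of [cohort_spec()] objects.
#' @param seed Integer seed.
#' @param reference Name of the reference cohort (default `"DM"`).
#' @return A single pooled data.frame (rows from all cohorts);
#'   `attr(, "true_cohort_log_or")` holds the named vector of true offsets.
#' @export
generate_pooled_cohorts <- function(specs, seed, reference = "DM") {
  stopifnot(reference %in% names(specs))
  ref_spec <- specs[[reference]]
  # Realize the reference covariates under the same stream the reference
  # cohort generation will use, so its tuned intercept is reproduced exactly.
  ref_seed <- derive_seed(seed, paste0("pooled-", reference))
  alpha_ref <- with_local_seed(ref_seed, {
    cov <- draw_covariates(ref_spec, ref_spec$n_patients)
    solve_intercept(risk_linear_predictor(cov, ref_spec$risk_coefficients),
                    ref_spec$cad_prevalence)
  })
  pieces <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    generate_cohort(sp, derive_seed(seed, paste0("pooled-", nm)),
                    intercept = alpha_ref + sp$cohort_log_or)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "true_cohort_log_or") <-
    vapply(specs, function(s) s$cohort_log_or, numeric(1))
  attr(out, "reference_intercept") <- alpha_ref
  out
}

#' Fill chart-review labels on a cohort
#'
#' Emulates gold-standard chart review: the selected patients' `reviewed_label`
#' is set to their true CAD status (review is modeled as error-free). Two
#' designs are supported: a simple random sample of fixed size, and review of
#' every patient the CAD screen flags as possible CAD.
#'
#' @param records Generator output (must carry `true_cad`).
#' @param design Either `list(type = "random", n = <size>)` or
#'   `list(type = "screen_positive_all")`.
#' @param rule A [screen_rule()]; required for the screen-positive design.
#' @param seed Integer seed (used by the random design).
#' @return `records` with `reviewed_label` filled for the reviewed patients
#'   (existing labels are preserved).
#' @export
sample_chart_review <- function(records, design, rule = screen_rule(), seed = 1L) {
  stopifnot(is.data.frame(records), "true_cad" %in% names(records))
  type <- design$type %||% stop("design$type is required")
  if (identical(type, "random")) {
    n <- design$n
    eligible <- which(is.na(records$reviewed_label))
    if (!is.numeric(n) || n < 0) stop("design$n must be a nonnegative count")
    if (n > length(eligible))
      stop(sprintf("requested %d reviews but only %d eligible records", n,
                   length(eligible)))
    idx <- with_local_seed(seed, sample(eligible, n))
  } else if (identical(type, "screen_positive_all")) {
    sr <- apply_screen(records, rule)
    idx <- which(sr$possible_cad == 1)
  } else {
    stop(sprintf("unknown review design type '%s'", type))
  }
  records$reviewed_label[idx] <- records$true_cad[idx]
  records
}

#' Parse serialized LDL values
#'
#' @param x Character vector of semicolon-separated LDL values (mg/dL); `""`
#'   means no LDL in the EMR.
#' @return List of numeric vectors (possibly empty).
#' @export
parse_ldl_values <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}
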