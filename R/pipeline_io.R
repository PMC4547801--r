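#' Pipeline run configuration
#'
#' @param specs Named list of [cohort_spec()]s (default [default_cohort_specs()]
#'   at `scale`); must include the training cohort and, for the association
#'   stage, the reference cohort.
#' @param seed Top-level integer seed; per-stage child seeds are derived from
#'   it by a stable hash so adding a stage does not perturb earlier stages.
#' @param target_ppv Common target PPV across cohorts, in (0, 1].
#' @param feature_sets Feature sets to run.
#' @param training_cohort Cohort used to develop the model (default `"RA"`,
#'   the low-prevalence cohort).
#' @param reference_cohort Reference for the association stage (default
#'   `"DM"`).
#' @param review Review design: `train_random_n` patients randomly reviewed in
#'   the training cohort (prevalence estimation), plus review of all its
#'   screen positives; `validation_random_n` named vector of random review
#'   sizes for the other cohorts.
#' @param scale Size multiplier passed to [default_cohort_specs()] when
#'   `specs` is `NULL`.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(specs = NULL, seed = 1L, target_ppv = 0.90,
                       feature_sets = c("structured_only", "structured_plus_nlp"),
                       training_cohort = "RA", reference_cohort = "DM",
                       review = list(train_random_n = 200,
                                     validation_random_n = c(IBD = 397, DM = 362)),
                       scale = 1, out_dir = tempfile("phecad_run_")) {
  if (is.null(specs)) specs <- default_cohort_specs(scale)
  if (target_ppv <= 0 || target_ppv > 1) stop("target_ppv must lie in (0, 1]")
  if (!length(specs)) stop("at least one cohort spec is required")
  if (!length(feature_sets)) stop("at least one feature set is required")
  if (!training_cohort %in% names(specs))
    stop("training_cohort must be one of the cohort specs")
  structure(list(specs = specs, seed = as.integer(seed),
                 target_ppv = target_ppv, feature_sets = feature_sets,
                 training_cohort = training_cohort,
                 reference_cohort = reference_cohort,
                 review = review, out_dir = out_dir),
            class = "run_config")
}

#' Run the full cross-cohort CAD analysis end-to-end
#'
#' Orchestrates every stage: generate the synthetic cohorts, apply the CAD
#' screen, simulate chart review (random sample plus all screen positives in
#' the training cohort; random samples in the validation cohorts), fit the
#' adaptive-LASSO phenotype model per feature set on the training cohort's
#' reviewed screen positives, calibrate a per-cohort cutoff at the common
#' target PPV, classify every cohort, compare feature sets, tabulate cohort
#' characteristics by classified CAD status, and fit the cross-cohort
#' association model. All artifacts are written under `config$out_dir`:
#'
#' * `patients_<cohort>.csv` -- generated cohort with screen flag and review
#'   labels;
#' * `classification_<cohort>.csv` -- probability and classification per
#'   patient (for each feature set);
#' * `model_<feature_set>.json`, `calibration_<cohort>_<feature_set>.json`;
#' * `comparison.csv` -- per cohort x feature set performance rows;
#' * `characteristics.csv` -- cohort characteristics by classified CAD;
#' * `association.json` -- unadjusted and adjusted cross-cohort odds ratios;
#' * `manifest.json` -- seed, config hash, package version, per-stage counts.
#'
#' Reruns with an identical config are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohorts`, `models`,
#'   `classifications`, `comparison`, `association`, `manifest`).
#' @export
run_cad_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, cohort, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for cohort '%s': %s",
                   name, cohort, conditionMessage(e)), call. = FALSE)
    })
  }
  rule <- screen_rule()
  log_counts <- list()

  cohorts <- lapply(names(config$specs), function(nm) {
    stage("generate", nm,
          generate_cohort(config$specs[[nm]], derive_seed(config$seed, paste0("gen-", nm))))
  })
  names(cohorts) <- names(config$specs)

  for (nm in names(cohorts)) {
    sr <- stage("screen", nm, apply_screen(cohorts[[nm]], rule))
    cohorts[[nm]]$possible_cad <- sr$possible_cad
    log_counts[[nm]] <- list(n = nrow(cohorts[[nm]]), screen_positive = sr$n_possible)
  }

  tc <- config$training_cohort
  cohorts[[tc]] <- stage("review", tc, {
    x <- sample_chart_review(cohorts[[tc]],
                             list(type = "random", n = config$review$train_random_n),
                             rule, derive_seed(config$seed, paste0("review-", tc)))
    sample_chart_review(x, list(type = "screen_positive_all"), rule)
  })
  for (nm in setdiff(names(cohorts), tc)) {
    nrev <- config$review$validation_random_n[[nm]] %||% 0
    nrev <- min(nrev, nrow(cohorts[[nm]]))
    if (nrev > 0) {
      cohorts[[nm]] <- stage("review", nm,
        sample_chart_review(cohorts[[nm]], list(type = "random", n = nrev),
                            rule, derive_seed(config$seed, paste0("review-", nm))))
    }
    log_counts[[nm]]$reviewed <- sum(!is.na(cohorts[[nm]]$reviewed_label))
  }
  log_counts[[tc]]$reviewed <- sum(!is.na(cohorts[[tc]]$reviewed_label))

  train <- cohorts[[tc]]
  train_fit <- train[train$possible_cad == 1 & !is.na(train$reviewed_label), , drop = FALSE]
  models <- lapply(config$feature_sets, function(fs) {
    stage("fit", tc, {
      fm <- build_features(train_fit, feature_set = fs)
      fit_adaptive_lasso(fm, train_fit$reviewed_label)
    })
  })
  names(models) <- config$feature_sets
  for (fs in config$feature_sets) {
    write_cad_model(models[[fs]], file.path(config$out_dir, paste0("model_", fs, ".json")))
  }

  classifications <- list()
  for (nm in names(cohorts)) {
    per_fs <- lapply(config$feature_sets, function(fs) {
      stage("classify", nm,
            classify_cohort(cohorts[[nm]], models[[fs]], rule, config$target_ppv))
    })
    names(per_fs) <- config$feature_sets
    classifications[[nm]] <- per_fs
    cls <- data.frame(patient_id = cohorts[[nm]]$patient_id,
                      cohort = nm, stringsAsFactors = FALSE)
    for (fs in config$feature_sets) {
      cls[[paste0("probability_", fs)]] <- round(per_fs[[fs]]$probabilities, 8)
      cls[[paste0("cad_", fs)]] <- per_fs[[fs]]$classified
      cal <- per_fs[[fs]]$calibration
      jsonlite::write_json(unclass(cal),
                           file.path(config$out_dir,
                                     sprintf("calibration_%s_%s.json", nm, fs)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    write.csv(cls, file.path(config$out_dir, paste0("classification_", nm, ".csv")),
              row.names = FALSE)
    write_patients(cohorts[[nm]],
                   file.path(config$out_dir, paste0("patients_", nm, ".csv")))
  }

  comparison <- NULL
  if (all(c("structured_only", "structured_plus_nlp") %in% config$feature_sets)) {
    rows <- list()
    for (nm in names(cohorts)) {
      cmp <- stage("evaluate", nm,
        compare_feature_sets(cohorts[[nm]], models$structured_only,
                             models$structured_plus_nlp, rule, config$target_ppv))
      for (r in cmp) {
        m <- r$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = r$cohort, feature_set = r$feature_set,
          sensitivity = m$sensitivity, specificity = m$specificity,
          ppv = m$ppv, npv = m$npv,
          n_classified_cad = r$n_classified_cad,
          pct_additional_classified = r$pct_additional_classified,
          attainable = r$attainable, stringsAsFactors = FALSE)
      }
    }
    comparison <- do.call(rbind, rows)
    write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
              row.names = FALSE)
  }

  fs_main <- if ("structured_plus_nlp" %in% config$feature_sets)
    "structured_plus_nlp" else config$feature_sets[[1]]
  pooled <- do.call(rbind, lapply(names(cohorts), function(nm) {
    x <- cohorts[[nm]]
    x$cad_classified <- classifications[[nm]][[fs_main]]$classified
    x
  }))
  rownames(pooled) <- NULL
  write.csv(cohort_characteristics(pooled),
            file.path(config$out_dir, "characteristics.csv"), row.names = FALSE)

  association <- NULL
  if (config$reference_cohort %in% names(cohorts) && length(cohorts) > 1) {
    association <- stage("associate", "pooled", {
      unadj <- adjusted_cohort_ors(pooled, "cad_classified",
                                   config$reference_cohort, adjusted = FALSE)
      adj <- adjusted_cohort_ors(pooled, "cad_classified",
                                 config$reference_cohort, adjusted = TRUE)
      list(unadjusted = unadj$comparisons, adjusted = adj$comparisons)
    })
    jsonlite::write_json(association, file.path(config$out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    seed = config$seed, target_ppv = config$target_ppv,
    feature_sets = config$feature_sets,
    training_cohort = tc, reference_cohort = config$reference_cohort,
    cohort_sizes = lapply(config$specs, function(s) s$n_patients),
    prevalences = lapply(config$specs, function(s) s$cad_prevalence),
    review = config$review,
    package_version = as.character(utils::packageVersion("phecad")),
    config_hash = config_hash(config),
    stage_counts = log_counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohorts = cohorts, models = models,
                 classifications = classifications, comparison = comparison,
                 association = association, manifest = manifest,
                 out_dir = config$out_dir))
}

# Stable hash of the reproducibility-relevant configuration.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(serialize_config(config), tmp)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(config) {
  list(seed = config$seed, target_ppv = config$target_ppv,
       feature_sets = as.list(config$feature_sets),
       training_cohort = config$training_cohort,
       reference_cohort = config$reference_cohort,
       review = list(train_random_n = config$review$train_random_n,
                     validation_random_n = as.list(config$review$validation_random_n)),
       specs = lapply(config$specs, spec_to_list))
}

# Cohort characteristics by classified CAD status (a Table of cohort
# demographics/comorbidities stratified CAD yes/no).
cohort_characteristics <- function(pooled) {
  rows <- list()
  for (nm in unique(pooled$cohort)) {
    x <- pooled[pooled$cohort == nm, ]
    for (status in c(1, 0)) {
      s <- x[x$cad_classified == status, ]
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = nm, cad = status, n = nrow(s),
        prevalence_pct = if (status == 1) prevalence(nrow(s), nrow(x)) else NA,
        mean_age = round(mean(s$age), 1),
        male_pct = round(100 * mean(s$sex == "M"), 1),
        white_pct = round(100 * mean(s$race == "white"), 1),
        black_pct = round(100 * mean(s$race == "black"), 1),
        htn_pct = round(100 * mean(s$htn), 1),
        hyperlipidemia_pct = round(100 * mean(s$hyperlipidemia), 1),
        ever_smoker_pct = round(100 * mean(s$ever_smoker), 1),
        mean_followup_months = round(mean(s$followup_months), 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read and write patient tables as CSV
#'
#' The on-disk dialect is UTF-8 CSV with a header row and one column per
#' feature: `patient_id`, `cohort`, demographics (`age`, `sex`, `race`,
#' `htn`, `hyperlipidemia`, `ever_smoker`, `followup_months`), one
#' `icd9_<code>` count column per code, `cpt_*` 0/1 flags,
#' `total_fact_count`, `nlp_*` 0/1 flags, `ldl_values`
#' (semicolon-separated mg/dL, empty string = none), and optionally
#' `true_cad`, `reviewed_label`, `possible_cad`. Unknown columns are
#' preserved on round trip.
#'
#' @param records Patient data.frame.
#' @param path CSV file path.
#' @return `write_patients()` returns `path` invisibly; `read_patients()`
#'   returns the patient data.frame.
#' @export
write_patients <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if (length(header) == 0) stop("empty patient file: ", path)
  mandatory <- c("patient_id", "cohort")
  missing_cols <- setdiff(mandatory, header)
  if (length(missing_cols))
    stop("patient file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  char_cols <- intersect(c("patient_id", "cohort", "sex", "race", "ldl_values"),
                         header)
  cc <- setNames(rep("character", length(char_cols)), char_cols)
  out <- read.csv(path, check.names = FALSE, colClasses = cc,
                  na.strings = "NA", fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
  if ("ldl_values" %in% names(out)) out$ldl_values[is.na(out$ldl_values)] <- ""
  out
}

spec_to_list <- function(spec) {
  list(name = spec$name, n_patients = spec$n_patients,
       cad_prevalence = spec$cad_prevalence,
       covariate_marginals = spec$covariate_marginals,
       signal_params = list(
         icd9_rates = as.list(spec$signal_params$icd9_rates),
         cpt = lapply(spec$signal_params$cpt, as.list),
         nlp = lapply(spec$signal_params$nlp, as.list),
         nlp_smoking = as.list(spec$signal_params$nlp_smoking),
         ldl = as.list(spec$signal_params$ldl),
         background_facts = as.list(spec$signal_params$background_facts)),
       risk_coefficients = as.list(spec$risk_coefficients),
       cohort_log_or = spec$cohort_log_or)
}

list_to_spec <- function(l) {
  sp <- l$signal_params
  cohort_spec(
    name = l$name, n_patients = l$n_patients, cad_prevalence = l$cad_prevalence,
    covariate_marginals = l$covariate_marginals,
    signal_params = list(
      icd9_rates = data.frame(code = as.character(unlist(sp$icd9_rates$code)),
                              rate_cad = as.numeric(unlist(sp$icd9_rates$rate_cad)),
                              rate_noncad = as.numeric(unlist(sp$icd9_rates$rate_noncad)),
                              stringsAsFactors = FALSE),
      cpt = lapply(sp$cpt, function(x) unlist(x)),
      nlp = lapply(sp$nlp, function(x) unlist(x)),
      nlp_smoking = unlist(sp$nlp_smoking),
      ldl = unlist(sp$ldl),
      background_facts = unlist(sp$background_facts)),
    risk_coefficients = unlist(l$risk_coefficients),
    cohort_log_or = l$cohort_log_or %||% 0)
}

#' Serialize cohort specs to and from YAML
#'
#' @param specs Named list of [cohort_spec()]s.
#' @param path YAML file path.
#' @return `write_cohort_specs()` returns `path` invisibly;
#'   `read_cohort_specs()` returns the named list of validated specs.
#' @export
write_cohort_specs <- function(specs, path) {
  yaml::write_yaml(lapply(specs, spec_to_list), path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_specs
#' @export
read_cohort_specs <- function(path) {
  lapply(yaml::read_yaml(path), list_to_spec)
}

#' Serialize a screen rule to and from YAML
#'
#' @param rule A [screen_rule()].
#' @param path YAML file path.
#' @return `write_screen_rule()` returns `path` invisibly;
#'   `read_screen_rule()` returns the validated rule.
#' @export
write_screen_rule <- function(rule, path) {
  stopifnot(inherits(rule, "screen_rule"))
  yaml::write_yaml(unclass(rule), path)
  invisible(path)
}

#' @rdname write_screen_rule
#' @export
read_screen_rule <- function(path) {
  l <- yaml::read_yaml(path)
  screen_rule(icd9_prefixes = as.character(unlist(l$icd9_prefixes)),
              nlp_concepts = as.character(unlist(l$nlp_concepts)),
              min_code_count = l$min_code_count,
              min_mention_count = l$min_mention_count)
}
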