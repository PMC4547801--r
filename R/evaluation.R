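#' Two-by-two confusion matrix
#'
#' @param predicted,truth Equal-length 0/1 vectors.
#' @return Object of class `confusion_matrix` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(predicted, truth) {
  p <- as.numeric(predicted); t <- as.numeric(truth)
  if (length(p) != length(t)) stop("predicted and truth differ in length")
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("predicted and truth must be strictly binary (0/1)")
  structure(list(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
                 fn = sum(p == 0 & t == 1), tn = sum(p == 0 & t == 0)),
            class = "confusion_matrix")
}

#' Performance metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)` and
#' NPV `tn/(tn+fn)`, reported as percentages rounded to one decimal. A metric
#' whose denominator is zero is reported as `NA` (not available), never as 0.
#' The raw fractions are stored alongside under `raw`.
#'
#' @param cm A [confusion()] matrix.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` (percent, one
#'   decimal) and `raw` (unrounded proportions).
#' @export
cad_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  raw <- list(sensitivity = frac(cm$tp, cm$tp + cm$fn),
              specificity = frac(cm$tn, cm$tn + cm$fp),
              ppv = frac(cm$tp, cm$tp + cm$fp),
              npv = frac(cm$tn, cm$tn + cm$fn))
  out <- lapply(raw, function(x) if (is.na(x)) NA_real_ else round(100 * x, 1))
  out$raw <- raw
  out
}

#' Percent additional patients classified
#'
#' Relative growth of the classified-CAD count when one pipeline variant is
#' compared against a reference variant, as a percentage of the reference
#' count, rounded to one decimal (e.g. 390 -> 457 is a 17.2% increase).
#'
#' @param n_reference Reference count (> 0).
#' @param n_new Comparison count.
#' @return Percentage, one decimal.
#' @export
pct_additional_classified <- function(n_reference, n_new) {
  if (!is.numeric(n_reference) || n_reference <= 0)
    stop("n_reference must be a positive count")
  round(100 * (n_new - n_reference) / n_reference, 1)
}

#' Baseline CAD definition: at least two ischemic heart disease codes
#'
#' The naive comparator rule: a patient is called CAD when their total count
#' of ICD9 codes in the ischemic heart disease families (410-414) reaches
#' `min_codes`, with no screening or modeling.
#'
#' @param records Patient data.frame with `icd9_<code>` columns.
#' @param min_codes Minimum total code count (default 2).
#' @param icd9_prefixes Code families counted (default 410-414).
#' @return Integer 0/1 vector per patient.
#' @export
baseline_icd9_rule <- function(records, min_codes = 2L,
                               icd9_prefixes = c("410", "411", "412", "413", "414")) {
  as.integer(matched_code_count(records, icd9_prefixes) >= min_codes)
}

#' Run the two-stage classifier on one cohort with one feature set
#'
#' Screen, score screen positives, calibrate the cutoff on the reviewed
#' screen-positive subset, then classify the whole cohort (screen negatives
#' are classified negative by construction -- the two-step rule).
#'
#' @param records One cohort's patient data.frame with `reviewed_label` filled
#'   for the reviewed subset.
#' @param model A fitted `cad_phenotype_model`.
#' @param rule A [screen_rule()].
#' @param target_ppv Target PPV for the cutoff.
#' @return List: `classified` (0/1 per patient), `probabilities` (NA for
#'   screen negatives), `calibration`, `screen` (the `screen_result`).
#' @export
classify_cohort <- function(records, model, rule = screen_rule(),
                            target_ppv = 0.90) {
  sr <- apply_screen(records, rule)
  pos <- sr$possible_cad == 1
  prob <- rep(NA_real_, nrow(records))
  classified <- integer(nrow(records))
  if (any(pos)) {
    prob[pos] <- score_cad(model, records[pos, , drop = FALSE])
    lab_pos <- pos & !is.na(records$reviewed_label)
    if (!any(lab_pos))
      stop("no reviewed screen-positive records to calibrate the cutoff on")
    cal <- calibrate_threshold(prob[lab_pos], records$reviewed_label[lab_pos],
                               target_ppv = target_ppv,
                               cohort = records$cohort[1])
    classified[pos] <- classify_cad(prob[pos], cal)
  } else {
    stop("no screen-positive records in cohort; nothing to classify")
  }
  list(classified = classified, probabilities = prob, calibration = cal,
       screen = sr)
}

#' Compare structured-only vs structured+NLP pipelines at matched PPV
#'
#' Runs the full two-stage classification twice on one cohort -- once with the
#' structured-only model and once with the structured+NLP model -- at the same
#' target PPV, computes the two-by-two metrics on the chart-reviewed subset,
#' and reports the percent additional patients classified CAD by the NLP
#' variant over the whole cohort (structured-only is the reference).
#'
#' @param records One cohort with reviewed labels filled.
#' @param model_structured,model_nlp Fitted models for the two feature sets.
#' @param rule A [screen_rule()].
#' @param target_ppv Common target PPV.
#' @param eval_subset_size Optional size of the random-review subset used for
#'   metric computation; `NULL` (default) uses every reviewed record.
#' @param seed Seed for the optional metric-subset draw.
#' @return List of two `performance_report`s (`structured_only`,
#'   `structured_plus_nlp`), each carrying cohort, feature set, metrics,
#'   confusion matrix, `n_classified_cad`, calibration, and (on the NLP arm)
#'   `pct_additional_classified`.
#' @export
compare_feature_sets <- function(records, model_structured, model_nlp,
                                 rule = screen_rule(), target_ppv = 0.90,
                                 eval_subset_size = NULL, seed = 1L) {
  run <- function(model, feature_set) {
    res <- classify_cohort(records, model, rule, target_ppv)
    reviewed <- which(!is.na(records$reviewed_label))
    if (!is.null(eval_subset_size) && eval_subset_size < length(reviewed)) {
      reviewed <- with_local_seed(derive_seed(seed, "eval-subset"),
                                  sort(sample(reviewed, eval_subset_size)))
    }
    cm <- confusion(res$classified[reviewed], records$reviewed_label[reviewed])
    structure(list(cohort = records$cohort[1], feature_set = feature_set,
                   metrics = cad_metrics(cm), confusion = cm,
                   n_classified_cad = sum(res$classified),
                   calibration = res$calibration,
                   attainable = res$calibration$attainable),
              class = "performance_report")
  }
  rep_s <- run(model_structured, "structured_only")
  rep_n <- run(model_nlp, "structured_plus_nlp")
  rep_n$pct_additional_classified <-
    pct_additional_classified(max(rep_s$n_classified_cad, 1),
                              rep_n$n_classified_cad)
  rep_s$pct_additional_classified <- 0.0
  list(structured_only = rep_s, structured_plus_nlp = rep_n)
}

#' @export
print.performance_report <- function(x, ...) {
  m <- x$metrics
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", v)
  cat(sprintf(
    "%s / %s: sens %s%%, spec %s%%, PPV %s%%, NPV %s%%, %d classified CAD%s%s\n",
    x$cohort, x$feature_set, fmt(m$sensitivity), fmt(m$specificity),
    fmt(m$ppv), fmt(m$npv), x$n_classified_cad,
    if (!is.null(x$pct_additional_classified))
      sprintf(" (+%.1f%% vs reference)", x$pct_additional_classified) else "",
    if (isTRUE(x$attainable)) "" else " [target PPV not attainable]"))
  invisible(x)
}
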