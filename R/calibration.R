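#' Calibrate the per-cohort probability cutoff to a target PPV
#'
#' The cross-cohort design anchors every cohort to the same positive
#' predictive value (90% by default): each cohort gets its own cutoff C on the
#' model's CAD probability, and a patient is classified CAD+ when their
#' probability is at least C. Candidate cutoffs are the observed unique
#' probabilities of the labeled (chart-reviewed) records; the chosen C is the
#' smallest candidate whose empirical PPV among classified positives meets the
#' target -- the maximal-sensitivity choice subject to the PPV constraint.
#' When no candidate qualifies, `attainable = FALSE` and the largest candidate
#' is reported with its achieved metrics.
#'
#' @param probabilities Numeric vector of model probabilities for labeled
#'   records.
#' @param labels 0/1 gold-standard labels, same length.
#' @param target_ppv Target PPV in (0, 1], default 0.90.
#' @param cohort Optional cohort label carried into the result.
#' @return Object of class `threshold_calibration`: `cohort`, `target_ppv`,
#'   `cutoff_c`, `achieved_ppv`, `achieved_sensitivity`,
#'   `n_classified_positive`, `attainable`.
#' @export
calibrate_threshold <- function(probabilities, labels, target_ppv = 0.90,
                                cohort = NA_character_) {
  p <- as.numeric(probabilities)
  y <- as.numeric(labels)
  if (length(p) == 0) stop("no labeled probabilities to calibrate on")
  if (length(p) != length(y)) stop("probabilities and labels differ in length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (!is.numeric(target_ppv) || target_ppv <= 0 || target_ppv > 1)
    stop("target_ppv must lie in (0, 1]")
  if (sum(y) == 0 && length(unique(p)) == 1)
    stop("degenerate calibration input: constant probabilities with no positive label")
  cand <- sort(unique(p))
  n_pos_total <- sum(y)
  best <- NULL
  for (cc in cand) {
    cls <- p >= cc
    ppv <- sum(y[cls]) / sum(cls)  # sum(cls) >= 1 since cc is observed
    if (ppv >= target_ppv) {
      best <- list(cutoff = cc, ppv = ppv,
                   sens = if (n_pos_total > 0) sum(y[cls]) / n_pos_total else NA_real_,
                   n_pos = sum(cls))
      break
    }
  }
  attainable <- !is.null(best)
  if (!attainable) {
    cc <- cand[length(cand)]
    cls <- p >= cc
    best <- list(cutoff = cc, ppv = sum(y[cls]) / sum(cls),
                 sens = if (n_pos_total > 0) sum(y[cls]) / n_pos_total else NA_real_,
                 n_pos = sum(cls))
  }
  structure(list(cohort = cohort, target_ppv = target_ppv,
                 cutoff_c = best$cutoff, achieved_ppv = best$ppv,
                 achieved_sensitivity = best$sens,
                 n_classified_positive = best$n_pos,
                 attainable = attainable),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "Cutoff calibration%s: C = %.4g (target PPV %.0f%%, %s), achieved PPV %.1f%%, sensitivity %.1f%%, %d classified CAD+\n",
    if (is.na(x$cohort)) "" else paste0(" [", x$cohort, "]"),
    x$cutoff_c, 100 * x$target_ppv,
    if (x$attainable) "attainable" else "NOT attainable",
    100 * x$achieved_ppv, 100 * x$achieved_sensitivity,
    x$n_classified_positive))
  invisible(x)
}

#' Classify patients at a calibrated cutoff
#'
#' @param probabilities Numeric vector of CAD probabilities.
#' @param calibration A [calibrate_threshold()] result.
#' @return Integer 0/1 vector: 1 iff probability >= `cutoff_c` (a probability
#'   exactly at the cutoff is classified positive).
#' @export
classify_cad <- function(probabilities, calibration) {
  stopifnot(inherits(calibration, "threshold_calibration"))
  as.integer(as.numeric(probabilities) >= calibration$cutoff_c)
}
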