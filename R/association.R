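#' Prevalence as a percentage
#'
#' @param n_cases,n_total Counts, `0 <= n_cases <= n_total`, `n_total > 0`.
#' @return `100 * n_cases / n_total`, rounded to one decimal.
#' @export
prevalence <- function(n_cases, n_total) {
  if (!is.numeric(n_total) || n_total <= 0) stop("n_total must be positive")
  if (n_cases < 0 || n_cases > n_total)
    stop("n_cases must lie in [0, n_total]")
  round(100 * n_cases / n_total, 1)
}

#' Two-by-two table for an exposure/reference comparison
#'
#' @param a Exposed cases; @param b exposed non-cases; @param c reference
#'   cases; @param d reference non-cases. All nonnegative integers.
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("two_by_two cells must be nonnegative integers")
  structure(as.list(cells), class = "two_by_two")
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `(a*d)/(b*c)`. Degenerate cells give `Inf` or 0 with a
#' `degenerate` flag rather than an error. The unrounded value is kept in
#' `raw`; `or` is rounded to two decimals for reporting.
#'
#' @param t A [two_by_two()].
#' @return List: `or` (2 dp), `raw`, `degenerate`.
#' @export
odds_ratio_2x2 <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  degenerate <- (t$b == 0 || t$c == 0 || t$a == 0 || t$d == 0)
  raw <- if (t$b == 0 || t$c == 0) {
    if (t$a == 0 || t$d == 0) NaN else Inf
  } else (t$a * t$d) / (t$b * t$c)
  list(or = round(raw, 2), raw = raw, degenerate = degenerate)
}

#' Woolf confidence interval for a 2x2 odds ratio
#'
#' Wald interval on the log-odds-ratio scale:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the standard
#' normal quantile at `(1 + level)/2`. Requires all four cells positive; for
#' tables with a zero cell set `continuity_correction = TRUE` to add 0.5 to
#' every cell (the Haldane-Anscombe correction) explicitly.
#'
#' @param t A [two_by_two()].
#' @param level Confidence level in (0, 1), default 0.95.
#' @param continuity_correction Add 0.5 to all cells before computing.
#' @return List: `lower`, `upper` (2 dp), `raw_lower`, `raw_upper`, `level`.
#' @export
woolf_ci <- function(t, level = 0.95, continuity_correction = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (continuity_correction) cells <- cells + 0.5
  if (any(cells == 0))
    stop("Woolf CI needs all cells > 0; rerun with continuity_correction = TRUE")
  if (level < 0 || level >= 1) stop("level must lie in [0, 1)")
  lor <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  z <- qnorm((1 + level) / 2)
  lo <- exp(lor - z * se); hi <- exp(lor + z * se)
  list(lower = round(lo, 2), upper = round(hi, 2),
       raw_lower = lo, raw_upper = hi, level = level)
}

#' Maximum-likelihood logistic regression with diagnostics
#'
#' Binomial GLM fit by iteratively reweighted least squares (Fisher scoring,
#' which for the canonical logit link is Newton-Raphson); the covariance is
#' the inverse observed information at the MLE. Rank-deficient designs and
#' (quasi-)separation are reported as errors naming the offending columns
#' rather than silently returning unstable estimates.
#'
#' @param design Numeric matrix or data.frame of covariates (no intercept
#'   column; one is added).
#' @param outcome 0/1 vector with both classes present.
#' @return List: `coefficients` (including `(Intercept)`), `vcov`,
#'   `converged`, `fit` (the underlying `glm` object).
#' @export
fit_logistic <- function(design, outcome) {
  x <- as.data.frame(design)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(y)) < 2)
    stop("degenerate outcome: both classes must be present")
  xm <- stats::model.matrix(~ ., data = x)
  qrx <- qr(xm)
  if (qrx$rank < ncol(xm)) {
    bad <- colnames(xm)[qrx$pivot[(qrx$rank + 1):ncol(xm)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = cbind(x, y = y), family = binomial(),
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)")
  cf <- coef(fit)
  big <- names(cf)[abs(cf) > 20]
  if (sep_warning && max(abs(cf[-1])) > 10)
    big <- union(big, names(cf[-1])[abs(cf[-1]) > 10])
  if (length(big))
    stop("possible separation: extreme coefficient(s) for ",
         paste(big, collapse = ", "))
  list(coefficients = cf, vcov = vcov(fit), converged = fit$converged,
       fit = fit)
}

#' Cross-cohort CAD odds ratios with DM as reference
#'
#' The clinical-example analysis: a logistic regression of classified CAD
#' status on cohort indicators (reference cohort's OR is 1 by construction),
#' optionally adjusted for age, sex, race (white/black/other), hypertension,
#' hyperlipidemia and ever-smoking. Odds ratios are `exp` of the fitted
#' coefficients with Wald 95% confidence intervals, reported to two decimals
#' alongside the raw values.
#'
#' @param records Pooled multi-cohort data.frame carrying `cohort`, the six
#'   covariates, and the classification column.
#' @param outcome_col Name of the 0/1 CAD column (e.g. `"cad_classified"` or
#'   `"true_cad"`).
#' @param reference Reference cohort label (default `"DM"`).
#' @param adjusted Adjust for the covariates (`TRUE`, default) or fit cohort
#'   indicators only (`FALSE`, reproduces the unadjusted 2x2 ORs).
#' @param level Confidence level for the Wald intervals.
#' @return Object of class `association_result`: data.frame `comparisons`
#'   (term, or, ci_lower, ci_upper, raw_*, adjusted), `coefficients`, `vcov`,
#'   `covariates`, `reference`.
#' @export
adjusted_cohort_ors <- function(records, outcome_col = "cad_classified",
                                reference = "DM", adjusted = TRUE,
                                level = 0.95) {
  stopifnot(outcome_col %in% names(records), "cohort" %in% names(records))
  cohorts <- unique(records$cohort)
  if (!reference %in% cohorts) stop("reference cohort absent from records")
  dat <- data.frame(cohort = factor(records$cohort,
                                    levels = c(reference,
                                               sort(setdiff(cohorts, reference)))))
  covariates <- character(0)
  if (adjusted) {
    covariates <- c("age", "sex", "race", "htn", "hyperlipidemia", "ever_smoker")
    missing_cols <- setdiff(covariates, names(records))
    if (length(missing_cols))
      stop("records lack adjustment covariate(s): ",
           paste(missing_cols, collapse = ", "))
    dat$age <- records$age
    dat$sex <- factor(records$sex, levels = c("F", "M"))
    dat$race <- factor(records$race, levels = c("white", "black", "other"))
    dat$htn <- records$htn
    dat$hyperlipidemia <- records$hyperlipidemia
    dat$ever_smoker <- records$ever_smoker
  }
  res <- fit_logistic(dat, records[[outcome_col]])
  cf <- res$coefficients
  se <- sqrt(diag(res$vcov))
  z <- qnorm((1 + level) / 2)
  terms <- setdiff(names(cf), "(Intercept)")
  comparisons <- data.frame(
    term = c(paste0("cohort", reference), terms),
    or = c(1, round(exp(cf[terms]), 2)),
    ci_lower = c(NA, round(exp(cf[terms] - z * se[terms]), 2)),
    ci_upper = c(NA, round(exp(cf[terms] + z * se[terms]), 2)),
    raw_or = c(1, exp(cf[terms])),
    raw_lower = c(NA, exp(cf[terms] - z * se[terms])),
    raw_upper = c(NA, exp(cf[terms] + z * se[terms])),
    adjusted = adjusted,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(comparisons = comparisons, coefficients = cf,
                 vcov = res$vcov, covariates = covariates,
                 reference = reference, level = level),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Cross-cohort CAD odds ratios (reference %s, %s):\n",
              x$reference,
              if (length(x$covariates)) "adjusted" else "unadjusted"))
  cohort_rows <- grepl("^cohort", x$comparisons$term)
  print(x$comparisons[cohort_rows, c("term", "or", "ci_lower", "ci_upper")],
        row.names = FALSE)
  invisible(x)
}
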