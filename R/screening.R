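#' Construct a CAD screen rule
#'
#' The screen is the first stage of the two-stage classifier: a deliberately
#' sensitive rule that partitions a cohort into "possible CAD" and "no CAD",
#' with the design goal of a negative predictive value of at least 99% so that
#' screen negatives can be safely treated as non-cases. A patient screens
#' positive when they carry at least `min_code_count` ICD9 codes in any of the
#' CAD code families, or at least `min_mention_count` NLP mentions of any CAD
#' concept.
#'
#' @param icd9_prefixes Character vector of dotted-ICD9 prefixes; a prefix
#'   matches a code that equals it or starts with `"<prefix>."` (so `"414"`
#'   matches `"414"`, `"414.0"`, `"414.01"`). Default: the ischemic heart
#'   disease families 410-414.
#' @param nlp_concepts Concept names whose `nlp_<concept>` flags count as CAD
#'   mentions.
#' @param min_code_count,min_mention_count Minimum evidence counts (both
#'   default 1).
#' @return An object of class `screen_rule`.
#' @export
screen_rule <- function(icd9_prefixes = c("410", "411", "412", "413", "414"),
                        nlp_concepts = c("cad", "cad_procedure",
                                         "cad_biomarker", "positive_stress"),
                        min_code_count = 1L, min_mention_count = 1L) {
  if (length(icd9_prefixes) == 0) stop("icd9_prefixes must be non-empty")
  if (length(nlp_concepts) == 0) stop("nlp_concepts must be non-empty")
  if (min_code_count < 1 || min_mention_count < 1)
    stop("minimum counts must be >= 1")
  structure(list(icd9_prefixes = as.character(icd9_prefixes),
                 nlp_concepts = as.character(nlp_concepts),
                 min_code_count = as.integer(min_code_count),
                 min_mention_count = as.integer(min_mention_count)),
            class = "screen_rule")
}

# Does a dotted ICD9 code string fall under any of the prefixes?
icd9_prefix_match <- function(codes, prefixes) {
  vapply(codes, function(code) {
    any(code == prefixes | startsWith(code, paste0(prefixes, ".")))
  }, logical(1), USE.NAMES = FALSE)
}

# Sum, per patient, the icd9_<code> columns whose code matches the prefixes.
matched_code_count <- function(records, prefixes) {
  icd_cols <- grep("^icd9_", names(records), value = TRUE)
  codes <- sub("^icd9_", "", icd_cols)
  keep <- icd_cols[icd9_prefix_match(codes, prefixes)]
  if (length(keep) == 0) return(rep(0L, nrow(records)))
  as.integer(rowSums(records[, keep, drop = FALSE]))
}

#' Apply the CAD screen to a cohort
#'
#' @param records Patient data.frame with `icd9_<code>` count columns and
#'   `nlp_<concept>` flag columns.
#' @param rule A [screen_rule()].
#' @return A list of class `screen_result`: `possible_cad` (0/1 per patient,
#'   aligned with `records`), `n_possible`, `n_no`.
#' @export
apply_screen <- function(records, rule = screen_rule()) {
  stopifnot(inherits(rule, "screen_rule"), is.data.frame(records))
  nlp_cols <- paste0("nlp_", rule$nlp_concepts)
  missing_cols <- setdiff(nlp_cols, names(records))
  if (length(missing_cols)) {
    offender <- if ("patient_id" %in% names(records) && nrow(records))
      records$patient_id[1] else "<unknown>"
    stop(sprintf("records (first patient_id %s) lack required columns: %s",
                 offender, paste(missing_cols, collapse = ", ")))
  }
  code_count <- matched_code_count(records, rule$icd9_prefixes)
  mention_count <- if (length(nlp_cols) == 1L) records[[nlp_cols]]
                   else rowSums(records[nlp_cols])
  flag <- as.integer(code_count >= rule$min_code_count |
                       mention_count >= rule$min_mention_count)
  structure(list(possible_cad = flag,
                 n_possible = sum(flag), n_no = sum(flag == 0)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("CAD screen: %d possible CAD, %d no CAD (%.1f%% screen positive)\n",
              x$n_possible, x$n_no,
              100 * x$n_possible / (x$n_possible + x$n_no)))
  invisible(x)
}

#' Negative predictive value of the screen on reviewed records
#'
#' Among chart-reviewed patients the screen calls negative, the fraction whose
#' gold-standard label is non-CAD. This is the quantity the screen's design
#' goal (NPV >= 99%) is stated in.
#'
#' @param screen_result Output of [apply_screen()] on `records`.
#' @param records The same patient data.frame, with `reviewed_label` filled
#'   for the reviewed subset.
#' @return List: `npv` in [0, 1], plus the count `numerator` (label-0 screen
#'   negatives) and `denominator` (labeled screen negatives).
#' @export
evaluate_screen_npv <- function(screen_result, records) {
  stopifnot(inherits(screen_result, "screen_result"),
            length(screen_result$possible_cad) == nrow(records))
  labeled_neg <- !is.na(records$reviewed_label) & screen_result$possible_cad == 0
  denom <- sum(labeled_neg)
  if (denom == 0)
    stop("NPV undefined: no labeled screen-negative records")
  num <- sum(records$reviewed_label[labeled_neg] == 0)
  list(npv = num / denom, numerator = num, denominator = denom)
}
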