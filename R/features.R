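#' Build the phenotype-model feature matrix
#'
#' Encodes patient records into the variable set of the final CAD algorithm:
#'
#' * structured -- count of coronary-atherosclerosis codes (`414.x`), count of
#'   other ischemic heart disease codes (`410.x`-`413.x`), total number of
#'   coded facts, CAD codes normalized by total utilization (CAD-family count
#'   divided by total fact count, 0 when the record holds no facts), a
#'   CABG-or-PCI procedure flag, an echocardiogram-performed flag, EMR
#'   follow-up time in months, age, mean LDL with a paired "no LDL values in
#'   EMR" indicator, and hypertension;
#' * NLP -- concept-mention flags for coronary artery disease, CAD procedures,
#'   never smoker and current smoker (dropped when
#'   `feature_set = "structured_only"`).
#'
#' All columns, binary flags included, are standardized to mean 0, SD 1 so
#' fitted coefficients are comparable across variable types; when a
#' `standardization` from a fitted model is supplied its training means/SDs
#' are reused (the scoring path). Records with no LDL values get the training
#' mean filled in, which standardizes to exactly 0 -- the neutral value -- and
#' carry the indicator instead. Zero-variance columns are dropped from
#' training (and recorded, so scoring drops the same ones).
#'
#' @param records Patient data.frame (generator output or [read_patients()]).
#' @param feature_set `"structured_plus_nlp"` (default) or
#'   `"structured_only"`.
#' @param standardization Optional standardization object from a previous
#'   [build_features()] call (training statistics) for scoring.
#' @return Object of class `feature_matrix`: `x` (standardized numeric
#'   matrix), `feature_names`, `provenance` (`"structured"`/`"nlp"` per
#'   column), `standardization` (list: `center`, `scale`, `ldl_fill`,
#'   `feature_set`, `dropped`).
#' @export
build_features <- function(records,
                           feature_set = c("structured_plus_nlp", "structured_only"),
                           standardization = NULL) {
  feature_set <- match.arg(feature_set)
  raw <- build_raw_features(records, feature_set)
  if (is.null(standardization)) {
    ldl_fill <- mean(raw$mean_ldl[raw$no_ldl == 0])
    if (is.nan(ldl_fill)) ldl_fill <- 0
    raw$mean_ldl[raw$no_ldl == 1] <- ldl_fill
    x <- as.matrix(raw)
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    dropped <- colnames(x)[scl == 0 | !is.finite(scl)]
    if (length(dropped))
      message("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
    keep <- setdiff(colnames(x), dropped)
    std <- list(center = ctr[keep], scale = scl[keep], ldl_fill = ldl_fill,
                feature_set = feature_set, dropped = dropped)
  } else {
    if (!identical(standardization$feature_set, feature_set))
      stop(sprintf("standardization was built for feature_set '%s', not '%s'",
                   standardization$feature_set, feature_set))
    missing_cols <- setdiff(names(standardization$center), names(raw))
    if (length(missing_cols))
      stop("records cannot provide training feature(s): ",
           paste(missing_cols, collapse = ", "))
    raw$mean_ldl[raw$no_ldl == 1] <- standardization$ldl_fill
    x <- as.matrix(raw)
    keep <- names(standardization$center)
    std <- standardization
  }
  x <- x[, keep, drop = FALSE]
  if (any(!is.finite(x)))
    stop("non-finite feature values after encoding")
  z <- sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
  rownames(z) <- records$patient_id
  structure(list(x = z,
                 feature_names = keep,
                 provenance = feature_provenance()[keep],
                 standardization = std),
            class = "feature_matrix")
}

# Provenance (structured vs NLP) of every possible feature column.
feature_provenance <- function() {
  c(icd9_cad = "structured", icd9_ihd = "structured",
    icd9_total = "structured", icd9_normalized = "structured",
    cabg_pci = "structured", echocardiogram = "structured",
    followup_months = "structured", age = "structured",
    mean_ldl = "structured", no_ldl = "structured", htn = "structured",
    nlp_cad = "nlp", nlp_cad_procedure = "nlp",
    nlp_never_smoker = "nlp", nlp_current_smoker = "nlp")
}

# Unstandardized feature construction; mean_ldl is NA-free only after the
# no-LDL fill applied by build_features().
build_raw_features <- function(records, feature_set) {
  need <- c("total_fact_count", "followup_months", "age", "htn",
            "cpt_cabg", "cpt_pci", "cpt_echocardiogram", "ldl_values")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack required column(s): ", paste(missing_cols, collapse = ", "))
  cad_cnt <- matched_code_count(records, "414")
  ihd_cnt <- matched_code_count(records, c("410", "411", "412", "413"))
  grp_cnt <- matched_code_count(records, c("410", "411", "412", "413", "414"))
  total <- records$total_fact_count
  ldl <- parse_ldl_values(records$ldl_values)
  no_ldl <- as.integer(lengths(ldl) == 0)
  mean_ldl <- vapply(ldl, function(v) if (length(v)) mean(v) else NA_real_,
                     numeric(1))
  out <- data.frame(
    icd9_cad = cad_cnt, icd9_ihd = ihd_cnt, icd9_total = total,
    icd9_normalized = ifelse(total > 0, grp_cnt / total, 0),
    cabg_pci = as.integer(records$cpt_cabg == 1 | records$cpt_pci == 1),
    echocardiogram = as.integer(records$cpt_echocardiogram == 1),
    followup_months = records$followup_months,
    age = records$age,
    mean_ldl = mean_ldl,
    no_ldl = no_ldl,
    htn = as.integer(records$htn == 1))
  if (feature_set == "structured_plus_nlp") {
    nlp_need <- c("nlp_cad", "nlp_cad_procedure", "nlp_never_smoker",
                  "nlp_current_smoker")
    missing_cols <- setdiff(nlp_need, names(records))
    if (length(missing_cols))
      stop("records lack required NLP column(s): ",
           paste(missing_cols, collapse = ", "))
    for (nm in nlp_need) out[[nm]] <- as.integer(records[[nm]] == 1)
  }
  out
}
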