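test_that("confusion matrices count the four cells correctly", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  x <- c(1, 0, 1, 0, 1)
  agree <- confusion(x, x)
  expect_equal(agree$fp + agree$fn, 0L)
  flip <- confusion(1 - x, x)
  expect_equal(flip$tp + flip$tn, 0L)
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
  expect_error(confusion(c(1, 0, 1), c(1, 0)), "length")
})

test_that("metrics follow the 2x2 definitions with NA for empty denominators", {
  m <- cad_metrics(confusion(c(rep(1, 10), rep(0, 90)),
                             c(rep(1, 9), 0, rep(0, 90))))
  expect_equal(m$ppv, 90.0)
  cm <- structure(list(tp = 73L, fp = 8L, fn = 27L, tn = 892L),
                  class = "confusion_matrix")
  m2 <- cad_metrics(cm)
  expect_equal(m2$sensitivity, 73.0)
  expect_equal(m2$specificity, round(100 * 892 / 900, 1))
  expect_equal(m2$raw$ppv, 73 / 81)
  none_pos <- cad_metrics(confusion(c(0, 0, 0), c(1, 0, 0)))
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$npv, round(100 * 2 / 3, 1))
  x <- c(1, 1, 0, 0, 1)
  perfect <- cad_metrics(confusion(x, x))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv), rep(100, 4))
})

test_that("percent additional classified reproduces the worked examples", {
  expect_equal(pct_additional_classified(390, 457), 17.2)
  expect_equal(pct_additional_classified(15392, 16962), 10.2)
  expect_equal(pct_additional_classified(100, 100), 0.0)
  expect_error(pct_additional_classified(0, 10), "positive")
})

test_that("the two-code baseline rule counts ischemic heart disease codes", {
  expect_equal(baseline_icd9_rule(make_records(1, `icd9_414.01` = 2L)), 1L)
  expect_equal(baseline_icd9_rule(make_records(1, `icd9_414.01` = 1L)), 0L)
  expect_equal(baseline_icd9_rule(make_records(1)), 0L)
  # codes accumulate across families
  two_families <- make_records(1, `icd9_410.9` = 1L, `icd9_413.9` = 1L)
  expect_equal(baseline_icd9_rule(two_families), 1L)
  expect_equal(baseline_icd9_rule(two_families, min_codes = 3), 0L)
})

test_that("feature-set comparison is self-consistent on a synthetic cohort", {
  rec <- shared_cohort()
  tr <- rec[rec$possible_cad == 1 & !is.na(rec$reviewed_label), ]
  m_s <- fit_adaptive_lasso(build_features(tr, feature_set = "structured_only"),
                            tr$reviewed_label)
  m_n <- fit_adaptive_lasso(build_features(tr), tr$reviewed_label)
  cmp <- compare_feature_sets(rec, m_s, m_n, target_ppv = 0.9)

  # identical models in both arms give exactly zero additional classification
  same <- compare_feature_sets(rec, m_s, m_s, target_ppv = 0.9)
  expect_equal(same$structured_plus_nlp$pct_additional_classified, 0.0)

  for (r in cmp) {
    cm <- r$confusion
    m <- r$metrics
    expect_equal(m$sensitivity, round(100 * cm$tp / (cm$tp + cm$fn), 1))
    expect_equal(m$ppv, round(100 * cm$tp / (cm$tp + cm$fp), 1))
    if (r$attainable) expect_gte(r$calibration$achieved_ppv, 0.9)
  }
  expect_equal(cmp$structured_plus_nlp$pct_additional_classified,
               pct_additional_classified(
                 max(cmp$structured_only$n_classified_cad, 1),
                 cmp$structured_plus_nlp$n_classified_cad))
})

test_that("screen negatives are classified negative by the two-step rule", {
  rec <- shared_cohort()
  tr <- rec[rec$possible_cad == 1 & !is.na(rec$reviewed_label), ]
  model <- fit_adaptive_lasso(build_features(tr), tr$reviewed_label)
  res <- classify_cohort(rec, model, target_ppv = 0.9)
  screen_neg <- res$screen$possible_cad == 0
  expect_true(all(res$classified[screen_neg] == 0))
  expect_true(all(is.na(res$probabilities[screen_neg])))
  expect_true(all(!is.na(res$probabilities[!screen_neg])))
})
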