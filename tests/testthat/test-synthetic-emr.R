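test_that("default cohort specs carry the documented marginals and validate", {
  specs <- default_cohort_specs()
  expect_named(specs, c("RA", "IBD", "DM"))
  expect_equal(specs$DM$covariate_marginals$p_htn, 0.806)
  expect_equal(specs$RA$covariate_marginals$p_female, 0.791)
  expect_equal(specs$RA$cad_prevalence, 0.05)
  expect_equal(specs$IBD$cad_prevalence, 0.042)
  expect_equal(specs$DM$cad_prevalence, 0.261)
  expect_equal(specs$DM$n_patients, 65099L)
  for (s in specs) expect_silent(validate_cohort_spec(s))
})

test_that("spec validation rejects degenerate fields by name", {
  specs <- default_cohort_specs(scale = 0.01)
  bad <- specs$RA; bad$cad_prevalence <- 0
  expect_error(validate_cohort_spec(bad), "cad_prevalence")
  bad$cad_prevalence <- 1
  expect_error(validate_cohort_spec(bad), "cad_prevalence")
  bad <- specs$RA; bad$n_patients <- 0
  expect_error(validate_cohort_spec(bad), "n_patients")
  bad <- specs$RA; bad$signal_params$icd9_rates$rate_cad[1] <- -1
  expect_error(validate_cohort_spec(bad), "signal_params")
  bad <- specs$RA
  bad$signal_params$nlp$cad <- c(cad = 0.1, noncad = 0.5)
  expect_error(validate_cohort_spec(bad), "CAD-conditional")
})

test_that("generation is reproducible and leaves the caller's RNG alone", {
  spec <- default_cohort_specs(scale = 0.02)$IBD
  set.seed(99); before <- runif(1)
  a <- generate_cohort(spec, 7)
  b <- generate_cohort(spec, 7)
  expect_identical(a, b)
  c <- generate_cohort(spec, 8)
  expect_false(identical(a$true_cad, c$true_cad))
  set.seed(99); expect_identical(before, runif(1))
})

test_that("marginal prevalence and covariate frequencies match the spec at n = 5000", {
  spec <- default_cohort_specs()$DM
  spec$n_patients <- 5000L
  rec <- generate_cohort(spec, 1)
  expect_equal(nrow(rec), 5000L)
  tol3sd <- function(p) 3 * sqrt(p * (1 - p) / 5000)
  expect_lt(abs(mean(rec$true_cad) - 0.26), tol3sd(0.26) + 0.001)
  cm <- spec$covariate_marginals
  expect_lt(abs(mean(rec$sex == "F") - cm$p_female), tol3sd(cm$p_female))
  expect_lt(abs(mean(rec$htn) - cm$p_htn), tol3sd(cm$p_htn))
  expect_lt(abs(mean(rec$hyperlipidemia) - cm$p_hyperlipidemia),
            tol3sd(cm$p_hyperlipidemia))
  expect_lt(abs(mean(rec$ever_smoker) - cm$p_ever_smoker),
            tol3sd(cm$p_ever_smoker))
  expect_lt(abs(mean(rec$race == "black") - cm$p_black), tol3sd(cm$p_black))
})

test_that("every CAD-indicative feature has higher mean under true CAD", {
  spec <- default_cohort_specs()$DM
  spec$n_patients <- 5000L
  rec <- generate_cohort(spec, 2)
  cad <- rec$true_cad == 1
  indicative <- c(grep("^icd9_", names(rec), value = TRUE),
                  paste0("cpt_", names(spec$signal_params$cpt)),
                  paste0("nlp_", names(spec$signal_params$nlp)))
  for (col in indicative) {
    expect_gte(mean(rec[[col]][cad]), mean(rec[[col]][!cad]))
  }
  expect_true(all(rec$total_fact_count >=
                    rowSums(rec[, grep("^icd9_", names(rec))])))
})

test_that("an NLP flag emitted under the null carries no association with CAD", {
  spec <- default_cohort_specs()$DM
  spec$n_patients <- 8000L
  spec$signal_params$nlp$cad_biomarker <- c(cad = 0.10, noncad = 0.10)
  rec <- generate_cohort(spec, 3)
  t <- table(factor(rec$nlp_cad_biomarker, 0:1), factor(rec$true_cad, 0:1))
  lor <- log((t[2, 2] * t[1, 1]) / (t[1, 2] * t[2, 1]))
  se <- sqrt(sum(1 / t))
  expect_lt(abs(lor), 3 * se)
})

test_that("a logistic refit on the generating covariates recovers the truth", {
  spec <- default_cohort_specs()$DM
  spec$n_patients <- 20000L
  rec <- generate_cohort(spec, 11)
  fit <- glm(true_cad ~ age + I(sex == "M") + htn + hyperlipidemia + ever_smoker,
             data = rec, family = binomial())
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  truth <- spec$risk_coefficients[c("age", "male", "htn", "hyperlipidemia",
                                    "ever_smoker")]
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("chart review fills exactly the requested labels with true status", {
  spec <- default_cohort_specs()$RA   # full-size RA-like cohort
  rec <- generate_cohort(spec, 5)
  expect_equal(nrow(rec), 4453L)
  rev1 <- sample_chart_review(rec, list(type = "random", n = 200), seed = 10)
  expect_equal(sum(!is.na(rev1$reviewed_label)), 200L)
  expect_identical(rev1$reviewed_label[!is.na(rev1$reviewed_label)],
                   rev1$true_cad[!is.na(rev1$reviewed_label)])
  rev2 <- sample_chart_review(rec, list(type = "random", n = 200), seed = 10)
  expect_identical(rev1, rev2)
  expect_error(sample_chart_review(rec, list(type = "random", n = nrow(rec) + 1)),
               "eligible")
  expect_error(sample_chart_review(rec, list(type = "bogus")), "unknown")
})

test_that("screen-positive-all review of an evidence-free cohort labels nobody", {
  rec <- make_records(20)
  out <- sample_chart_review(rec, list(type = "screen_positive_all"))
  expect_equal(sum(!is.na(out$reviewed_label)), 0L)
})

test_that("pooled generation fixes the cohort effect exactly and reproducibly", {
  specs <- default_cohort_specs(scale = 0.05)
  pooled <- generate_pooled_cohorts(specs, seed = 4)
  expect_setequal(unique(pooled$cohort), c("RA", "IBD", "DM"))
  lor <- attr(pooled, "true_cohort_log_or")
  expect_equal(unname(lor["IBD"]), log(0.34))
  expect_equal(unname(lor["DM"]), 0)
  expect_identical(pooled$true_cad,
                   generate_pooled_cohorts(specs, seed = 4)$true_cad)
  # DM piece is anchored at its own prevalence target
  dm <- pooled[pooled$cohort == "DM", ]
  expect_lt(abs(mean(dm$true_cad) - 0.261),
            3 * sqrt(0.261 * 0.739 / nrow(dm)) + 0.002)
})

test_that("LDL serialization round-trips through the parser", {
  x <- c("110.5;98.2", "", "120")
  parsed <- parse_ldl_values(x)
  expect_equal(lengths(parsed), c(2L, 0L, 1L))
  expect_equal(parsed[[1]], c(110.5, 98.2))
})
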