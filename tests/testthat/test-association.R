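test_that("prevalence reproduces the printed cohort percentages", {
  expect_equal(prevalence(457, 10974), 4.2)
  expect_equal(prevalence(16962, 65099), 26.1)
  expect_equal(prevalence(0, 10), 0.0)
  expect_error(prevalence(1, 0), "positive")
  expect_error(prevalence(11, 10), "n_cases")
})

test_that("2x2 odds ratios reproduce the printed cross-cohort comparisons", {
  ibd <- two_by_two(457, 10517, 16962, 48136)
  expect_equal(odds_ratio_2x2(ibd)$or, 0.12)
  ra <- two_by_two(245, 4208, 16962, 48136)
  expect_equal(odds_ratio_2x2(ra)$or, 0.17)
  expect_equal(odds_ratio_2x2(two_by_two(7, 13, 7, 13))$or, 1.0)
  expect_error(two_by_two(-1, 2, 3, 4), "nonnegative")
})

test_that("degenerate 2x2 cells flag and yield infinite or zero odds ratios", {
  res <- odds_ratio_2x2(two_by_two(5, 0, 3, 7))
  expect_true(res$degenerate)
  expect_equal(res$raw, Inf)
  res0 <- odds_ratio_2x2(two_by_two(0, 5, 3, 7))
  expect_true(res0$degenerate)
  expect_equal(res0$raw, 0)
})

test_that("Woolf intervals reproduce the printed confidence limits", {
  ibd <- two_by_two(457, 10517, 16962, 48136)
  ci <- woolf_ci(ibd)
  expect_equal(c(ci$lower, ci$upper), c(0.11, 0.14))
  ra <- two_by_two(245, 4208, 16962, 48136)
  ci2 <- woolf_ci(ra)
  expect_equal(c(ci2$lower, ci2$upper), c(0.15, 0.19))
  # level -> 0 collapses the interval onto the odds ratio
  ci0 <- woolf_ci(ibd, level = 0)
  expect_equal(ci0$raw_lower, odds_ratio_2x2(ibd)$raw, tolerance = 1e-12)
  expect_equal(ci0$raw_upper, odds_ratio_2x2(ibd)$raw, tolerance = 1e-12)
})

test_that("zero cells require the explicit continuity correction", {
  t0 <- two_by_two(5, 0, 3, 7)
  expect_error(woolf_ci(t0), "continuity")
  ci <- woolf_ci(t0, continuity_correction = TRUE)
  expect_true(is.finite(ci$raw_lower) && is.finite(ci$raw_upper))
  expect_true(ci$raw_lower <= ci$raw_upper)
})

test_that("odds ratios are row-scale invariant and CIs tighten with size", {
  t1 <- two_by_two(12, 40, 30, 100)
  t2 <- two_by_two(12 * 3, 40 * 3, 30, 100)   # scale the exposed row
  expect_equal(odds_ratio_2x2(t1)$raw, odds_ratio_2x2(t2)$raw, tolerance = 1e-12)
  widths <- vapply(c(1, 2, 5, 10), function(k) {
    ci <- woolf_ci(two_by_two(12 * k, 40 * k, 30 * k, 100 * k))
    log(ci$raw_upper) - log(ci$raw_lower)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("a single-binary-covariate logistic fit equals the cross-product OR", {
  set.seed(808)
  for (i in 1:100) {
    cells <- rpois(4, 30) + 1     # all cells positive
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    exposed <- c(rep(1, cells[1] + cells[2]), rep(0, cells[3] + cells[4]))
    case <- c(rep(1, cells[1]), rep(0, cells[2]),
              rep(1, cells[3]), rep(0, cells[4]))
    fit <- fit_logistic(data.frame(exposed = exposed), case)
    expect_lt(abs(exp(fit$coefficients["exposed"]) - odds_ratio_2x2(t)$raw),
              1e-8)
  }
})

test_that("logistic diagnostics catch degenerate designs", {
  expect_error(fit_logistic(data.frame(x = rnorm(20)), rep(0, 20)),
               "degenerate")
  x <- rnorm(50)
  expect_error(fit_logistic(data.frame(a = x, b = 2 * x), rbinom(50, 1, 0.5)),
               "aliased")
  # complete separation
  xs <- c(rep(-2, 25), rep(2, 25))
  ys <- c(rep(0, 25), rep(1, 25))
  expect_error(fit_logistic(data.frame(x = xs), ys), "separation")
})

test_that("covariate-free cohort ORs equal the 2x2 cross-product ratios", {
  pooled <- rbind(
    data.frame(cohort = "DM", cad_classified = rep(c(1, 0), c(300, 700))),
    data.frame(cohort = "IBD", cad_classified = rep(c(1, 0), c(40, 760))),
    data.frame(cohort = "RA", cad_classified = rep(c(1, 0), c(30, 470))))
  res <- adjusted_cohort_ors(pooled, "cad_classified", adjusted = FALSE)
  cmp <- res$comparisons
  expect_equal(cmp$or[cmp$term == "cohortDM"], 1.0)
  ibd_raw <- cmp$raw_or[cmp$term == "cohortIBD"]
  expect_lt(abs(ibd_raw - odds_ratio_2x2(two_by_two(40, 760, 300, 700))$raw),
            1e-6)
  ra_raw <- cmp$raw_or[cmp$term == "cohortRA"]
  expect_lt(abs(ra_raw - odds_ratio_2x2(two_by_two(30, 470, 300, 700))$raw),
            1e-6)
  expect_true(all(cmp$raw_lower[-1] <= cmp$raw_or[-1] &
                    cmp$raw_or[-1] <= cmp$raw_upper[-1]))
})

test_that("the adjusted model recovers the generator's cohort effect", {
  specs <- lapply(default_cohort_specs(scale = 0.25),
                  function(s) s)
  pooled <- generate_pooled_cohorts(specs, seed = 21)
  res <- adjusted_cohort_ors(pooled, "true_cad", reference = "DM",
                             adjusted = TRUE)
  cf <- res$coefficients
  se <- sqrt(diag(res$vcov))
  expect_lt(abs(cf["cohortIBD"] - log(0.34)), 3 * se["cohortIBD"])
  expect_lt(abs(cf["cohortRA"] - log(0.37)), 3 * se["cohortRA"])
  # covariate effects are recovered too
  expect_lt(abs(cf["age"] - log(1.05)), 3 * se["age"])
  expect_lt(abs(cf["hyperlipidemia"] - log(2.48)), 3 * se["hyperlipidemia"])
})
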