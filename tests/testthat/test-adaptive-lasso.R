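test_that("the unpenalized limit of the path matches an independent Newton MLE", {
  set.seed(101)
  n <- 400; p <- 6
  z <- scale(matrix(rnorm(n * p), n, p))
  beta_true <- c(1.2, -0.8, 0.5, 0, 0, 0)
  y <- rbinom(n, 1, plogis(-0.5 + z %*% beta_true))
  fm <- make_feature_matrix(z)
  fit <- fit_adaptive_lasso(fm, y, lambda_grid = 0)
  oracle <- oracle_logistic_mle(z, y)
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - oracle)), 1e-6)
})

test_that("degenerate or malformed inputs are rejected", {
  z <- scale(matrix(rnorm(200), 50, 4))
  fm <- make_feature_matrix(z)
  expect_error(fit_adaptive_lasso(fm, rep(1, 50)), "degenerate")
  expect_error(fit_adaptive_lasso(fm, rep(0, 50)), "degenerate")
  expect_error(fit_adaptive_lasso(fm, c(rep(0, 25), rep(2, 25))), "0/1")
  expect_error(fit_adaptive_lasso(fm, rep(0:1, 10)), "length")
  fm$x[1, 1] <- NA
  expect_error(fit_adaptive_lasso(fm, rep(0:1, 25)), "non-finite")
})

test_that("BIC selection picks the path minimum and df nests along the path", {
  set.seed(202)
  n <- 500; p <- 10
  z <- scale(matrix(rnorm(n * p), n, p))
  y <- rbinom(n, 1, plogis(z %*% c(1, -1, 0.9, rep(0, 7))))
  fit <- fit_adaptive_lasso(make_feature_matrix(z), y)
  path <- fit$bic_path
  sel <- path[path$lambda == fit$lambda_selected, ]
  expect_equal(sel$bic, min(path$bic))
  expect_equal(sel$df, sum(fit$coefficients != 0) + 1L)
  # df is nonincreasing in lambda (path stored from large to small lambda)
  expect_true(all(diff(path$df) >= 0))
  expect_true(all(path$df >= 1))
})

test_that("the ridge pilot is defined under complete separation", {
  z <- scale(matrix(c(rep(-1, 20), rep(1, 20)), 40, 1))
  y <- c(rep(0, 20), rep(1, 20))
  init <- phecad:::ridge_logistic(z, y, 1e-3)
  expect_true(all(is.finite(c(init$b0, init$beta))))
  fit <- fit_adaptive_lasso(make_feature_matrix(z), y)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("compiled and reference coordinate-descent solvers agree", {
  set.seed(303)
  z <- scale(matrix(rnorm(150 * 4), 150, 4))
  y <- rbinom(150, 1, plogis(z %*% c(1, -0.5, 0, 0)))
  pen <- c(0.02, 0.02, 0.1, 0.1)
  a <- phecad:::penalized_logistic_cd(z, y, pen, 0, rep(0, 4))
  b <- phecad:::penalized_logistic_cd_r(z, y, pen, 0, rep(0, 4))
  expect_lt(abs(a$b0 - b$b0), 1e-10)
  expect_lt(max(abs(unlist(a$beta) - b$beta)), 1e-10)
})

test_that("the path agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(404)
  n <- 600; p <- 8
  z <- scale(matrix(rnorm(n * p), n, p))
  y <- rbinom(n, 1, plogis(-0.3 + z %*% c(1, -0.8, 0.6, rep(0, 5))))
  fm <- make_feature_matrix(z)
  init <- phecad:::ridge_logistic(z, y, 1e-3)
  w <- 1 / pmax(abs(init$beta), 1e-4)
  lam <- 0.02
  fit <- fit_adaptive_lasso(fm, y, lambda_grid = lam)
  # glmnet rescales penalty factors to sum to p, so match lambda accordingly
  g <- glmnet::glmnet(z, y, family = "binomial", alpha = 1,
                      penalty.factor = w, lambda = lam * sum(w) / p,
                      standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(fit$coefficients - as.numeric(g$beta))), 2e-4)
  expect_lt(abs(fit$intercept - as.numeric(g$a0)), 2e-4)
})

test_that("reference-model scoring follows the published coefficient semantics", {
  model <- reference_cad_model()
  zero_patient <- make_records(1, age = 0, followup_months = 0,
                               total_fact_count = 0L, ldl_values = "0")
  zero_patient$htn <- 0L
  p0 <- score_cad(model, zero_patient)
  expect_equal(unname(p0), plogis(-10.19), tolerance = 1e-12)
  expect_equal(unname(p0), 3.754248e-05, tolerance = 1e-6)

  mention <- zero_patient; mention$nlp_cad <- 1L
  p1 <- score_cad(model, mention)
  expect_gt(p1, p0)
  expect_equal(unname(log(p1 / (1 - p1)) - log(p0 / (1 - p0))), 1.44,
               tolerance = 1e-8)
})

test_that("scores stay in (0,1) and respond monotonically to positive features", {
  model <- reference_cad_model()
  rec <- shared_cohort()[1:300, ]
  p <- score_cad(model, rec)
  expect_true(all(p > 0 & p < 1))
  bumped <- rec
  bumped$nlp_cad <- 1L   # coefficient 1.44 > 0
  expect_true(all(score_cad(model, bumped) >= p))
})

test_that("fitted models survive a JSON round trip and score identically", {
  rec <- shared_cohort()
  tr <- rec[rec$possible_cad == 1 & !is.na(rec$reviewed_label), ]
  fm <- build_features(tr)
  fit <- fit_adaptive_lasso(fm, tr$reviewed_label)
  path <- withr::local_tempfile(fileext = ".json")
  write_cad_model(fit, path)
  back <- read_cad_model(path)
  expect_equal(score_cad(back, rec[1:100, ]), score_cad(fit, rec[1:100, ]),
               tolerance = 1e-12)
  expect_equal(back$lambda_selected, fit$lambda_selected)
})
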