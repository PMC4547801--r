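#' Fit the adaptive-LASSO logistic phenotype model
#'
#' The phenotype model is an L1-penalized logistic regression with
#' per-coefficient adaptive weights, fit on chart-reviewed screen-positive
#' patients, with the penalty chosen by BIC:
#'
#' 1. an initial ridge-penalized logistic fit (small fixed penalty, defined
#'    even under separation) gives pilot coefficients;
#' 2. adaptive weights `w_j = 1 / |beta_init_j|^gamma` (intercept unpenalized;
#'    pilot magnitudes floored before inversion so weights stay finite);
#' 3. a penalized path over a log-spaced lambda grid is traced by iteratively
#'    reweighted least squares with coordinate descent, warm-started from the
#'    previous lambda;
#' 4. each path point gets `BIC = -2 loglik + df log(n)` with `df` = number of
#'    nonzero penalized coefficients + 1 (intercept);
#' 5. the minimum-BIC model is returned (ties go to the larger, sparser
#'    lambda).
#'
#' @param features A [build_features()] `feature_matrix` (training
#'   standardization is carried into the fitted model).
#' @param labels 0/1 outcome vector, one per feature row; at least two
#'   distinct values.
#' @param gamma Adaptive-weight exponent (default 1, the standard choice).
#' @param lambda_grid Optional numeric vector of penalties; by default 100
#'   log-spaced values from `lambda_max` (the smallest penalty that zeroes
#'   every penalized coefficient) down to `1e-4 * lambda_max`.
#' @param nlambda,lambda_min_ratio Grid size and lower-end ratio used when
#'   `lambda_grid` is `NULL`.
#' @param ridge_penalty Fixed ridge penalty for the pilot fit (on the
#'   standardized scale).
#' @param weight_floor Floor on pilot coefficient magnitudes before inversion.
#' @param tol Convergence tolerance: relative change in the penalized
#'   objective below `tol` stops the optimizer.
#' @param max_iter Iteration cap; hitting it raises a warning recorded in the
#'   model (`converged = FALSE`).
#' @return Object of class `cad_phenotype_model`: `intercept`, `coefficients`
#'   (standardized scale), `adaptive_weights`, `gamma`, `lambda_selected`,
#'   `bic_path` (data.frame with `lambda`, `df`, `loglik`, `bic`),
#'   `feature_set`, `standardization`, `provenance`, `converged`.
#' @export
fit_adaptive_lasso <- function(features, labels, gamma = 1,
                               lambda_grid = NULL, nlambda = 100,
                               lambda_min_ratio = 1e-4,
                               ridge_penalty = 1e-3, weight_floor = 1e-4,
                               tol = 1e-8, max_iter = 10000) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$x
  y <- as.numeric(labels)
  if (length(y) != nrow(x)) stop("labels length must equal feature rows")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2)
    stop("degenerate outcome: labels are constant, cannot fit phenotype model")
  if (any(!is.finite(x))) stop("non-finite feature values")
  n <- nrow(x)

  init <- ridge_logistic(x, y, ridge_penalty)
  w <- 1 / pmax(abs(init$beta), weight_floor)^gamma

  if (is.null(lambda_grid)) {
    p0 <- mean(y)
    grad0 <- abs(crossprod(x, y - p0)) / n
    lambda_max <- max(grad0 / w)
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                           length.out = nlambda))
  }
  lambda_grid <- sort(unique(as.numeric(lambda_grid)), decreasing = TRUE)

  beta <- rep(0, ncol(x))
  b0 <- stats::qlogis(mean(y))
  path <- vector("list", length(lambda_grid))
  fits <- vector("list", length(lambda_grid))
  all_converged <- TRUE
  for (k in seq_along(lambda_grid)) {
    fit <- penalized_logistic_cd(x, y, lambda_grid[k] * w,
                                 b0_init = b0, beta_init = beta,
                                 tol = tol, max_iter = max_iter)
    b0 <- fit$b0; beta <- fit$beta
    all_converged <- all_converged && fit$converged
    ll <- logistic_loglik(x, y, b0, beta)
    df <- sum(beta != 0) + 1L
    path[[k]] <- data.frame(lambda = lambda_grid[k], df = df, loglik = ll,
                            bic = -2 * ll + df * log(n))
    fits[[k]] <- fit
  }
  bic_path <- do.call(rbind, path)
  if (!all_converged)
    warning("penalized optimizer hit max_iter on at least one lambda")
  best <- which.min(bic_path$bic)  # ties: first index = largest lambda
  sel <- fits[[best]]
  structure(
    list(intercept = sel$b0,
         coefficients = setNames(sel$beta, colnames(x)),
         adaptive_weights = setNames(w, colnames(x)),
         gamma = gamma,
         lambda_selected = bic_path$lambda[best],
         bic_path = bic_path,
         feature_set = features$standardization$feature_set,
         standardization = features$standardization,
         provenance = features$provenance,
         converged = all_converged),
    class = "cad_phenotype_model")
}

#' @export
print.cad_phenotype_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("CAD phenotype model (%s): %d of %d features selected, lambda = %.4g, BIC = %.1f\n",
              x$feature_set, nz, length(x$coefficients), x$lambda_selected,
              min(x$bic_path$bic)))
  invisible(x)
}

# Bernoulli log-likelihood at (b0, beta) on standardized features.
logistic_loglik <- function(x, y, b0, beta) {
  eta <- drop(b0 + x %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Ridge-penalized logistic pilot fit by Newton-Raphson; intercept
# unpenalized. Penalty: (ridge/2) * ||beta||^2 added to -loglik/n.
ridge_logistic <- function(x, y, ridge, tol = 1e-10, max_iter = 200) {
  n <- nrow(x); p <- ncol(x)
  xa <- cbind(1, x)
  theta <- c(stats::qlogis(mean(y)), rep(0, p))
  pen <- diag(c(0, rep(ridge, p)), p + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(xa %*% theta)
    mu <- plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(xa, y - mu) / n - pen %*% theta
    hess <- crossprod(xa * wts, xa) / n + pen
    step <- solve(hess, grad)
    theta <- theta + step
    if (max(abs(grad)) < tol) break
  }
  list(b0 = theta[1], beta = theta[-1])
}

# Weighted-least-squares coordinate descent inside an IRLS outer loop for
# the L1-penalized logistic objective
#   (1/n) * -loglik + sum_j penalty_j * |beta_j|
# (penalty_j already folds lambda and the adaptive weight together).
# The compiled solver carries the path; the R implementation below is kept
# as an internal reference for equivalence testing.
penalized_logistic_cd <- function(x, y, penalty, b0_init, beta_init,
                                  tol = 1e-8, max_iter = 10000) {
  .cd_penalized_logistic(x, as.numeric(y), as.numeric(penalty),
                         b0_init, as.numeric(beta_init), tol,
                         as.integer(max_iter))
}

penalized_logistic_cd_r <- function(x, y, penalty, b0_init, beta_init,
                                    tol = 1e-8, max_iter = 10000) {
  n <- nrow(x); p <- ncol(x)
  b0 <- b0_init; beta <- beta_init
  obj <- function(b0, beta) {
    -logistic_loglik(x, y, b0, beta) / n + sum(penalty * abs(beta))
  }
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  last <- obj(b0, beta)
  iters <- 0L
  converged <- FALSE
  repeat {
    eta <- drop(b0 + x %*% beta)
    mu <- plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / wts
    # coordinate descent on the weighted quadratic approximation
    for (inner in 1:50) {
      delta <- 0
      r <- z - b0 - drop(x %*% beta)
      for (j in seq_len(p)) {
        xj <- x[, j]
        num <- sum(wts * xj * (r + xj * beta[j])) / n
        den <- sum(wts * xj^2) / n
        bj_new <- soft(num, penalty[j]) / den
        if (bj_new != beta[j]) {
          r <- r - xj * (bj_new - beta[j])
          delta <- max(delta, abs(bj_new - beta[j]))
          beta[j] <- bj_new
        }
      }
      b0_new <- sum(wts * (r + b0)) / sum(wts)
      r <- r - (b0_new - b0)
      delta <- max(delta, abs(b0_new - b0))
      b0 <- b0_new
      iters <- iters + 1L
      if (delta < 1e-11 || iters >= max_iter) break
    }
    cur <- obj(b0, beta)
    rel <- abs(last - cur) / (abs(last) + 1e-12)
    if (rel < tol) { converged <- TRUE; break }
    last <- cur
    if (iters >= max_iter) break
  }
  list(b0 = b0, beta = beta, converged = converged, iterations = iters)
}

#' Score patients with the fitted phenotype model
#'
#' Deterministically converts patient records to CAD probabilities: features
#' are rebuilt with the model's training standardization and the probability
#' is the inverse logit of the linear predictor,
#' `plogis(intercept + sum_j coef_j * z_j)`. Always strictly inside (0, 1).
#'
#' @param model A [fit_adaptive_lasso()] model (or [reference_cad_model()]).
#' @param records Patient data.frame encodable with the model's feature set.
#' @return Named numeric vector of probabilities (names = `patient_id`).
#' @export
score_cad <- function(model, records) {
  stopifnot(inherits(model, "cad_phenotype_model"))
  fm <- build_features(records, feature_set = model$feature_set,
                       standardization = model$standardization)
  eta <- drop(model$intercept + fm$x[, names(model$coefficients), drop = FALSE] %*%
                model$coefficients)
  setNames(plogis(eta), records$patient_id)
}

#' Serialize / restore a fitted phenotype model as JSON
#'
#' @param model A `cad_phenotype_model`.
#' @param path File path.
#' @return `write_cad_model()` returns `path` invisibly; `read_cad_model()`
#'   returns the restored model.
#' @export
write_cad_model <- function(model, path) {
  stopifnot(inherits(model, "cad_phenotype_model"))
  out <- list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    adaptive_weights = as.list(model$adaptive_weights),
    gamma = model$gamma,
    lambda_selected = model$lambda_selected,
    bic_path = model$bic_path,
    feature_set = model$feature_set,
    provenance = as.list(model$provenance),
    converged = model$converged,
    standardization = list(
      center = as.list(model$standardization$center),
      scale = as.list(model$standardization$scale),
      ldl_fill = model$standardization$ldl_fill,
      feature_set = model$standardization$feature_set,
      dropped = model$standardization$dropped))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cad_model
#' @export
read_cad_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(intercept = j$intercept,
         coefficients = unlist(j$coefficients),
         adaptive_weights = unlist(j$adaptive_weights),
         gamma = j$gamma,
         lambda_selected = j$lambda_selected,
         bic_path = as.data.frame(j$bic_path),
         feature_set = j$feature_set,
         provenance = unlist(j$provenance),
         converged = j$converged %||% TRUE,
         standardization = list(
           center = unlist(j$standardization$center),
           scale = unlist(j$standardization$scale),
           ldl_fill = j$standardization$ldl_fill,
           feature_set = j$standardization$feature_set,
           dropped = unlist(j$standardization$dropped))),
    class = "cad_phenotype_model")
}

#' Reference CAD algorithm coefficients
#'
#' Loads the published reference coefficient set for the CAD phenotype
#' algorithm (standardized coefficients, intercept -10.19, strongest positive
#' predictor the NLP coronary-artery-disease mention at 1.44) as a scoring
#' model. The standardization is the identity (each feature interpreted as
#' already on the standardized scale), so this model is a fixture for scoring
#' semantics, not a fit to any dataset.
#'
#' @return A `cad_phenotype_model` whose features are taken as standardized.
#' @export
reference_cad_model <- function() {
  path <- system.file("extdata", "cad_model_reference.json", package = "phecad")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(j$coefficients)
  structure(
    list(intercept = j$intercept,
         coefficients = coefs,
         adaptive_weights = setNames(rep(1, length(coefs)), names(coefs)),
         gamma = 1,
         lambda_selected = NA_real_,
         bic_path = data.frame(),
         feature_set = j$feature_set,
         provenance = unlist(j$provenance),
         converged = TRUE,
         standardization = list(
           center = setNames(rep(0, length(coefs)), names(coefs)),
           scale = setNames(rep(1, length(coefs)), names(coefs)),
           ldl_fill = 0, feature_set = j$feature_set, dropped = character(0))),
    class = "cad_phenotype_model")
}
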