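# Independent IRLS ridge-logistic oracle: Newton iterations on the exact
# objective mean-NLL + lambda/2 ||w||^2 (intercept and ICV unpenalized),
# run to 1e-10 on the same standardized design.
irls_ridge_oracle <- function(X, y, icv, lambda) {
  n <- nrow(X)
  Xs <- scale(X)
  Z <- cbind(1, scale(icv), Xs)
  D <- diag(c(0, 0, rep(1, ncol(X))))
  beta <- numeric(ncol(Z))
  for (it in 1:200) {
    eta <- drop(Z %*% beta)
    p <- plogis(eta)
    g <- drop(crossprod(Z, p - y)) / n + lambda * D %*% beta
    H <- crossprod(Z, Z * (p * (1 - p))) / n + lambda * D
    step <- solve(H, g)
    beta_new <- beta - step
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

make_small_problem <- function(n = 40, p = 10, seed = 31) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  w <- c(rep(1.2, 3), rep(0, p - 3))
  icv <- rnorm(n, 1.4e6, 1e5)
  y <- rbinom(n, 1, plogis(drop(scale(X) %*% w)))
  if (length(unique(y)) < 2 || min(table(y)) < 2) y[1:3] <- c(0L, 1L, 0L)
  list(X = X, y = y, icv = icv)
}

test_that("ridge fit (alpha = 0) matches the IRLS oracle to 1e-6", {
  pr <- make_small_problem()
  lambda <- 0.07
  f <- fit_score_model(pr$X, pr$y, pr$icv, alpha_mix = 0,
                       lambda_grid = lambda, cv = FALSE, tol = 1e-12)
  oracle <- irls_ridge_oracle(pr$X, pr$y, pr$icv, lambda)
  got <- c(f$model$intercept, f$model$icv_coef, unname(f$model$weights))
  expect_lt(max(abs(got - oracle)), 1e-6)
})

test_that("unpenalized fit (lambda = 0, p < n) matches glm", {
  pr <- make_small_problem(n = 80, p = 5, seed = 33)
  f <- fit_score_model(pr$X, pr$y, pr$icv, alpha_mix = 0.5,
                       lambda_grid = 0, cv = FALSE, tol = 1e-14)
  d <- data.frame(y = pr$y, icv = drop(scale(pr$icv)), scale(pr$X))
  gl <- stats::glm(y ~ ., data = d, family = binomial())
  got <- c(f$model$intercept, f$model$icv_coef, unname(f$model$weights))
  expect_lt(max(abs(got - unname(coef(gl)))), 1e-4)
})

test_that("elastic-net solution matches glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  pr <- make_small_problem(n = 60, p = 12, seed = 35)
  lambda <- 0.05; alpha <- 0.5
  f <- fit_score_model(pr$X, pr$y, pr$icv, alpha_mix = alpha,
                       lambda_grid = lambda, cv = FALSE, tol = 1e-13)
  Zs <- cbind(icv = drop(scale(pr$icv)), scale(pr$X))
  pf <- c(0, rep(1, ncol(pr$X)))
  # glmnet rescales penalty.factor to sum to nvars; undo that rescaling
  gn <- glmnet::glmnet(Zs, pr$y, family = "binomial", alpha = alpha,
                       lambda = lambda * sum(pf) / ncol(Zs),
                       penalty.factor = pf, standardize = FALSE,
                       thresh = 1e-14)
  got <- c(f$model$icv_coef, unname(f$model$weights))
  ref <- as.numeric(coef(gn))[-1]
  expect_lt(max(abs(got - ref)), 1e-4)
  expect_lt(abs(f$model$intercept - as.numeric(coef(gn))[1]), 1e-4)
})

test_that("full-shrinkage limit zeroes all penalized weights", {
  pr <- make_small_problem()
  f <- fit_score_model(pr$X, pr$y, pr$icv, alpha_mix = 0.5,
                       lambda_grid = 1e4, cv = FALSE)
  expect_true(all(f$model$weights == 0))
  s <- project_scores(f$model, pr$X, pr$icv)
  eta <- f$model$intercept +
    f$model$icv_coef * as.numeric(pr$icv - f$model$icv_mean) / f$model$icv_sd
  expect_equal(s, plogis(eta), tolerance = 1e-12)
})

test_that("objective decreases monotonically across optimizer iterations", {
  pr <- make_small_problem(seed = 37)
  for (lam in c(0.5, 0.05, 0.005)) {
    f <- fit_score_model(pr$X, pr$y, pr$icv, alpha_mix = 0.5,
                         lambda_grid = lam, cv = FALSE)
    expect_true(all(diff(f$model$obj_trace) <= 1e-10))
  }
})

test_that("solution is invariant to row permutation of the training data", {
  pr <- make_small_problem(seed = 39)
  set.seed(1); perm <- sample(nrow(pr$X))
  f1 <- fit_score_model(pr$X, pr$y, pr$icv, alpha_mix = 0.5,
                        lambda_grid = 0.05, cv = FALSE, tol = 1e-12)
  f2 <- fit_score_model(pr$X[perm, ], pr$y[perm], pr$icv[perm],
                        alpha_mix = 0.5, lambda_grid = 0.05, cv = FALSE,
                        tol = 1e-12)
  expect_lt(max(abs(f1$model$weights - f2$model$weights)), 1e-6)
  expect_lt(abs(f1$model$intercept - f2$model$intercept), 1e-6)
})

test_that("training-data projection reproduces in-sample fitted probabilities", {
  pr <- make_small_problem(seed = 41)
  f <- fit_score_model(pr$X, pr$y, pr$icv, alpha_mix = 0.5,
                       lambda_grid = 0.05, cv = FALSE)
  s <- project_scores(f$model, pr$X, pr$icv)
  std <- scale(pr$X)
  std[, attr(std, "scaled:scale") == 0] <- 0
  eta <- f$model$intercept +
    f$model$icv_coef * as.numeric(scale(pr$icv)) +
    as.numeric(std %*% f$model$weights)
  expect_equal(unname(s), plogis(eta), tolerance = 1e-10)
})

test_that("AUC is the Mann-Whitney pair-counting statistic", {
  set.seed(5)
  labels <- rep(c(1, 0), c(4, 6))
  for (r in 1:5) {
    s <- sample(c(rnorm(8), rnorm(2)))  # include ties occasionally
    s[1] <- s[5]
    expect_equal(auc_mw(s, labels), auc_pairs(s, labels))
  }
  expect_equal(auc_mw(rep(0.4, 10), labels), 0.5)       # uninformative scorer
  expect_equal(auc_mw(labels * 2 + 1, labels), 1.0)      # perfect separation
})

test_that("errors: single class, non-finite features, schema mismatch", {
  pr <- make_small_problem()
  expect_error(fit_score_model(pr$X, rep(1, nrow(pr$X)), pr$icv),
               "single class")
  Xb <- pr$X; Xb[3, "f04"] <- NA
  expect_error(fit_score_model(Xb, pr$y, pr$icv), "f04")
  f <- fit_score_model(pr$X, pr$y, pr$icv, lambda_grid = 0.1, cv = FALSE)
  expect_error(project_scores(f$model, pr$X[, -2], pr$icv[1:40]),
               "schema mismatch")
})

test_that("projected scores live strictly in (0,1) and increase in the linear predictor", {
  m <- structure(list(weights = c(f1 = 0.8), intercept = 0, icv_coef = 0,
                      feature_names = "f1", feature_mean = c(f1 = 0),
                      feature_sd = c(f1 = 1), icv_mean = 0, icv_sd = 1,
                      lambda = 0, alpha_mix = 0.5), class = "score_model")
  x <- matrix(seq(-8, 8, length.out = 41), dimnames = list(NULL, "f1"))
  s <- project_scores(m, x, rep(0, 41))
  expect_true(all(s > 0 & s < 1))
  expect_true(all(diff(s) > 0))
  m0 <- m; m0$weights[] <- 0
  expect_equal(project_scores(m0, x, rep(0, 41)), rep(0.5, 41))
})

test_that("LOO CV: equals per-fold refits and selects separating penalties on strong signal", {
  cc <- simulate_case_control(12, 10, delta_case = 3,
                              schema = tiny_schema(50L, 8L), seed = 43)
  fit <- fit_score_model(cc$features, cc$labels, cc$covariates$icv,
                         n_lambda = 6)
  expect_gte(max(fit$cv$cv_auc), 0.9)
  expect_equal(fit$cv$insample_auc, 1.0)
  # selected lambda is the largest attaining the maximum
  top <- fit$cv$lambda_grid[fit$cv$cv_auc >= max(fit$cv$cv_auc) - 1e-12]
  expect_equal(fit$cv$selected_lambda, max(top))
  # loo_cv_auc at the selected penalty agrees with the CV report
  a <- loo_cv_auc(cc$features, cc$labels, cc$covariates$icv,
                  lambda = fit$cv$selected_lambda)
  sel <- which(fit$cv$lambda_grid == fit$cv$selected_lambda)
  expect_equal(a, fit$cv$cv_auc[sel])
})
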