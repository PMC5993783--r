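# Penalized logistic discriminant: morphometry -> 0-1 neuroanatomical score.
# The solver is proximal-gradient (FISTA with backtracking and a monotone
# safeguard) on the standardized design; intercept and ICV are unpenalized.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the normalized Mann-Whitney U statistic of case versus
#' control scores, with ties counted 1/2.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stable mean negative log-likelihood of the logistic model
nll_mean <- function(eta, y) {
  mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
}

# elastic-net logistic objective; pen = indices of penalized coefficients
enet_objective <- function(theta, Z, y, pen, lambda, alpha) {
  w <- theta[pen]
  nll_mean(drop(Z %*% theta), y) +
    lambda * (alpha * sum(abs(w)) + (1 - alpha) / 2 * sum(w^2))
}

# FISTA with backtracking; monotone in the objective (accelerated step is
# rejected in favour of a plain descent step whenever it would increase f).
# The iteration itself runs compiled (src/fista.cpp); this wrapper sets the
# initial step from a spectral-norm estimate.
fista_enet <- function(Z, y, pen, lambda, alpha, init, tol = 1e-8,
                       max_iter = 10000L, step0 = NULL) {
  n <- nrow(Z); k <- ncol(Z)
  lam1 <- lambda * alpha; lam2 <- lambda * (1 - alpha)
  if (is.null(step0)) {
    # spectral norm by a few power iterations; backtracking corrects any
    # underestimate of the Lipschitz constant
    v <- sin(seq_len(k)); v <- v / sqrt(sum(v^2))  # deterministic start
    for (i in 1:8) {
      v <- drop(crossprod(Z, Z %*% v))
      v <- v / sqrt(sum(v^2))
    }
    s2 <- sum((Z %*% v)^2)
    step0 <- 1 / (s2 / (4 * n) + lam2 + 1e-12)
  }
  res <- fista_enet_cpp(Z, as.numeric(y), as.integer(pen) - 1L,
                        lam1, lam2,
                        if (is.null(init)) numeric(k) else as.numeric(init),
                        tol, as.integer(max_iter), step0)
  res$theta <- drop(res$theta)
  res
}

standardize_cols <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
  keep <- sdv > 0
  Xs <- sweep(X, 2, mu)
  Xs <- sweep(Xs, 2, ifelse(keep, sdv, 1), `/`)
  Xs[, !keep] <- 0
  list(x = Xs, mean = mu, sd = sdv, keep = keep)
}

check_features <- function(features) {
  bad <- which(!apply(features, 2, function(x) all(is.finite(x))))
  if (length(bad))
    stop("non-finite feature values in column(s): ",
         paste(colnames(features)[bad] %||% bad, collapse = ", "))
  invisible(features)
}

fit_enet_logistic <- function(features, labels, icv, lambda, alpha_mix,
                              tol, max_iter, init = NULL) {
  std <- standardize_cols(features)
  icv_mu <- mean(icv); icv_sd <- stats::sd(icv)
  if (icv_sd <= 0) stop("ICV has zero variance")
  icv_s <- (icv - icv_mu) / icv_sd
  Z <- cbind(1, icv_s, std$x)
  pen <- 2L + seq_len(ncol(features))
  if (is.null(init)) {
    # start at the covariate-only optimum so early iterations are not spent
    # crawling the unpenalized coordinates
    base <- suppressWarnings(
      stats::glm.fit(Z[, 1:2, drop = FALSE], labels,
                     family = stats::binomial()))
    b0 <- base$coefficients
    b0[!is.finite(b0)] <- 0
    init <- c(pmin(pmax(b0, -5), 5), numeric(length(pen)))
  }
  fit <- if (alpha_mix > 0 && length(pen) > 500L)
    fista_enet_active(Z, labels, pen, lambda, alpha_mix, init = init,
                      tol = tol, max_iter = max_iter)
  else
    fista_enet(Z, labels, pen, lambda, alpha_mix, init = init,
               tol = tol, max_iter = max_iter)
  list(fit = fit, std = std, icv_mean = icv_mu, icv_sd = icv_sd)
}

# Active-set wrapper for large sparse problems: solve on a working set of
# features, then verify the full KKT conditions (|grad_j| <= lambda*alpha at
# zero coefficients) and expand with violators until none remain. The
# solution is identical to the full-design solve; only the work differs.
fista_enet_active <- function(Z, y, pen, lambda, alpha, init, tol, max_iter) {
  n <- nrow(Z)
  lam1 <- lambda * alpha; lam2 <- lambda * (1 - alpha)
  unpen <- setdiff(seq_len(ncol(Z)), pen)
  p_hat <- stats::plogis(drop(Z %*% init))
  g0 <- abs(drop(crossprod(Z, p_hat - y))[pen] / n)
  active <- pen[g0 > 0.9 * lam1 | init[pen] != 0]
  theta <- init
  trace <- NULL
  fit <- NULL
  for (round in 1:50) {
    work <- c(unpen, active)
    Zw <- Z[, work, drop = FALSE]
    pw <- which(work %in% active)
    fit <- fista_enet(Zw, y, pw, lambda, alpha, init = theta[work],
                      tol = tol, max_iter = max_iter)
    theta[] <- 0
    theta[work] <- fit$theta
    trace <- c(trace, list(fit$trace))
    p_hat <- stats::plogis(drop(Z %*% theta))
    grad <- drop(crossprod(Z, p_hat - y))[pen] / n + lam2 * theta[pen]
    viol <- pen[abs(grad) > lam1 + 1e-9 & theta[pen] == 0]
    viol <- setdiff(viol, active)
    if (!length(viol)) break
    active <- sort(c(active, viol))
  }
  list(theta = theta, objective = fit$objective,
       trace = unlist(trace), converged = fit$converged,
       n_iter = fit$n_iter, step = fit$step, n_active = length(active))
}

model_from_fit <- function(f, features, lambda, alpha_mix) {
  th <- f$fit$theta
  structure(list(
    weights = stats::setNames(th[-(1:2)], colnames(features)),
    intercept = th[1], icv_coef = th[2],
    feature_names = colnames(features),
    feature_mean = f$std$mean, feature_sd = f$std$sd,
    icv_mean = f$icv_mean, icv_sd = f$icv_sd,
    lambda = lambda, alpha_mix = alpha_mix,
    converged = f$fit$converged, n_iter = f$fit$n_iter,
    objective = f$fit$objective, obj_trace = f$fit$trace
  ), class = "score_model")
}

default_lambda_grid <- function(features, labels, icv, alpha_mix,
                                n_lambda = 30L) {
  std <- standardize_cols(features)
  icv_s <- (icv - mean(icv)) / stats::sd(icv)
  base <- stats::glm.fit(cbind(1, icv_s), labels,
                         family = stats::binomial())
  r <- labels - base$fitted.values
  lmax <- max(abs(drop(crossprod(std$x, r))) / length(labels))
  lmax <- lmax / max(alpha_mix, 1e-3)
  # glmnet convention: shallower grid when p >= n
  ratio <- if (ncol(features) >= nrow(features)) 1e-2 else 1e-4
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Fit the penalized logistic score model
#'
#' Trains an elastic-net-penalized logistic discriminant of case status on
#' standardized morphometric features, with an unpenalized intercept and an
#' unpenalized (standardized) intracranial-volume covariate, so that overall
#' brain size does not drive the classification. The penalty strength is
#' selected by leave-one-out cross-validated AUC over a descending lambda
#' grid (warm-started); ties go to the larger, more parsimonious lambda.
#'
#' The objective is the mean negative log-likelihood plus
#' `lambda * (alpha |w|_1 + (1 - alpha)/2 |w|_2^2)` over feature weights only.
#'
#' @param features n-by-p numeric matrix with column names.
#' @param labels 0/1 vector, 1 = case; both classes must be present.
#' @param icv numeric vector of intracranial volumes.
#' @param alpha_mix elastic-net mixing in `[0, 1]` (1 = lasso; default 0.5).
#' @param lambda_grid optional decreasing penalty grid; default 30 log-spaced
#'   values from the data-derived `lambda_max` down 4 decades.
#' @param n_lambda grid length when `lambda_grid` is `NULL`.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum proximal-gradient iterations per fit.
#' @param cv if `FALSE`, skip cross-validation and fit at `lambda_grid[1]`.
#' @return list with `model` (class `score_model`) and `cv` (class
#'   `cv_report`: grid, per-lambda LOO AUC, selected lambda, in-sample AUC).
#' @export
fit_score_model <- function(features, labels, icv, alpha_mix = 0.5,
                            lambda_grid = NULL, n_lambda = 30L,
                            tol = 1e-8, max_iter = 10000L, cv = TRUE) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%05d", seq_len(ncol(features)))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; need both cases and controls")
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")
  check_features(features)
  stopifnot(length(icv) == nrow(features), alpha_mix >= 0, alpha_mix <= 1)
  if (is.null(lambda_grid))
    lambda_grid <- default_lambda_grid(features, labels, icv, alpha_mix,
                                       n_lambda)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  # full-data solution path (descending lambda, warm-started); the fold fits
  # below start from the path solution at the same lambda
  path <- vector("list", length(lambda_grid))
  init <- NULL
  for (l in seq_along(lambda_grid)) {
    path[[l]] <- fit_enet_logistic(features, labels, icv, lambda_grid[l],
                                   alpha_mix, tol, max_iter, init = init)
    init <- path[[l]]$fit$theta
    if (!cv || length(lambda_grid) == 1L) break
  }

  cv_auc <- rep(NA_real_, length(lambda_grid))
  if (cv && length(lambda_grid) > 1L) {
    held_out <- loo_heldout_scores(features, labels, icv, lambda_grid,
                                   alpha_mix, tol, max_iter,
                                   path_init = lapply(path,
                                                      function(f) f$fit$theta))
    cv_auc <- apply(held_out, 2, auc_mw, labels = labels)
    sel <- which(cv_auc >= max(cv_auc) - 1e-12)[1]  # grid descending: largest
  } else sel <- 1L

  lambda <- lambda_grid[sel]
  model <- model_from_fit(path[[sel]], features, lambda, alpha_mix)
  insample <- auc_mw(project_scores(model, features, icv), labels)
  cv_report <- structure(list(lambda_grid = lambda_grid, cv_auc = cv_auc,
                              selected_lambda = lambda,
                              insample_auc = insample),
                         class = "cv_report")
  list(model = model, cv = cv_report)
}

# Held-out scores for every subject and every lambda: each fold is
# standardized once and warm-started down the (descending) lambda grid.
loo_heldout_scores <- function(features, labels, icv, lambda_grid, alpha_mix,
                               tol, max_iter, path_init = NULL) {
  n <- nrow(features)
  held_out <- matrix(NA_real_, n, length(lambda_grid))
  for (i in seq_len(n)) {
    Xtr <- features[-i, , drop = FALSE]
    ytr <- labels[-i]
    std <- standardize_cols(Xtr)
    icv_mu <- mean(icv[-i]); icv_sd <- stats::sd(icv[-i])
    if (icv_sd <= 0) stop("fit failed with subject ", i,
                          " held out: ICV has zero variance")
    Z <- cbind(1, (icv[-i] - icv_mu) / icv_sd, std$x)
    pen <- 2L + seq_len(ncol(Xtr))
    base <- suppressWarnings(
      stats::glm.fit(Z[, 1:2, drop = FALSE], ytr,
                     family = stats::binomial()))
    b0 <- base$coefficients
    b0[!is.finite(b0)] <- 0
    init <- c(pmin(pmax(b0, -5), 5), numeric(length(pen)))
    xs_i <- (features[i, ] - std$mean) / ifelse(std$keep, std$sd, 1)
    xs_i[!std$keep] <- 0
    for (l in seq_along(lambda_grid)) {
      if (!is.null(path_init)) init <- path_init[[l]]
      fit <- tryCatch(
        if (alpha_mix > 0 && length(pen) > 500L)
          fista_enet_active(Z, ytr, pen, lambda_grid[l], alpha_mix,
                            init = init, tol = tol, max_iter = max_iter)
        else
          fista_enet(Z, ytr, pen, lambda_grid[l], alpha_mix, init = init,
                     tol = tol, max_iter = max_iter),
        error = function(e) stop("fit failed with subject ", i,
                                 " held out: ", conditionMessage(e)))
      init <- fit$theta
      eta <- fit$theta[1] +
        fit$theta[2] * (icv[i] - icv_mu) / icv_sd +
        sum(fit$theta[-(1:2)] * xs_i)
      held_out[i, l] <- stats::plogis(eta)
    }
  }
  held_out
}

#' Leave-one-out cross-validated AUC at a fixed penalty
#'
#' Each subject is scored by a model trained without it (standardization
#' recomputed from the training rows only); the AUC is the Mann-Whitney
#' statistic of held-out case versus control scores.
#'
#' @inheritParams fit_score_model
#' @param lambda penalty strength.
#' @return AUC in `[0, 1]`.
#' @export
loo_cv_auc <- function(features, labels, icv, lambda, alpha_mix = 0.5,
                       tol = 1e-8, max_iter = 10000L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%05d", seq_len(ncol(features)))
  labels <- as.integer(labels)
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 subjects for leave-one-out CV")
  scores <- loo_heldout_scores(features, labels, icv, lambda, alpha_mix,
                               tol, max_iter)[, 1]
  auc_mw(scores, labels)
}

#' Project neuroanatomical scores onto new subjects
#'
#' Applies the trained discriminative weights, with the training-set
#' standardization, to a new feature matrix; no refitting or recalibration.
#' Scores are `sigmoid(intercept + icv_coef * ICV_std + sum_j w_j x_std_j)`,
#' strictly inside (0, 1).
#'
#' @param model a `score_model`.
#' @param features matrix whose columns match the training schema by name.
#' @param icv intracranial volumes for the new subjects.
#' @return numeric vector of scores in (0, 1).
#' @export
project_scores <- function(model, features, icv) {
  stopifnot(inherits(model, "score_model"))
  features <- as.matrix(features)
  if (is.null(colnames(features)) &&
      ncol(features) == length(model$feature_names))
    colnames(features) <- model$feature_names
  missing_f <- setdiff(model$feature_names, colnames(features))
  extra_f <- setdiff(colnames(features), model$feature_names)
  if (length(missing_f) || length(extra_f))
    stop("feature schema mismatch; missing: [",
         paste(utils::head(missing_f, 5), collapse = ", "),
         if (length(missing_f) > 5) ", ..." else "", "]; extra: [",
         paste(utils::head(extra_f, 5), collapse = ", "),
         if (length(extra_f) > 5) ", ..." else "", "]")
  features <- features[, model$feature_names, drop = FALSE]
  stopifnot(length(icv) == nrow(features))
  keep <- model$feature_sd > 0
  Xs <- sweep(features, 2, model$feature_mean)
  Xs <- sweep(Xs, 2, ifelse(keep, model$feature_sd, 1), `/`)
  Xs[, !keep] <- 0
  eta <- model$intercept +
    model$icv_coef * (icv - model$icv_mean) / model$icv_sd +
    drop(Xs %*% model$weights)
  stats::plogis(eta)
}

#' @export
print.score_model <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat("Penalized logistic score model\n",
      "  features: ", length(x$weights), " (", nz, " nonzero weights)\n",
      "  lambda = ", format(x$lambda), ", alpha = ", x$alpha_mix, "\n",
      "  intercept = ", format(x$intercept),
      ", ICV coefficient = ", format(x$icv_coef), "\n", sep = "")
  invisible(x)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("LOO-CV over", length(x$lambda_grid), "lambdas; selected lambda =",
      format(x$selected_lambda), "\n  best LOO AUC =",
      format(max(x$cv_auc, na.rm = TRUE)), "; in-sample AUC =",
      format(x$insample_auc), "\n")
  invisible(x)
}
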