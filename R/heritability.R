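# SNP-heritability: genetic relationship matrix from dosages and restricted
# maximum likelihood variance components (average-information updates with an
# expectation-maximization fallback), with delta-method SEs and a boundary
# likelihood-ratio test.

#' Genetic relationship matrix from dosages
#'
#' The standard allele-frequency-standardized estimator:
#' `A_jk = (1/M) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the sample alternate-allele frequency of SNP i. Missing dosages
#' are mean-imputed per SNP; SNPs with minor-allele frequency below `maf_min`
#' are excluded and counted.
#'
#' @param genotypes a `genotypes` object or a subjects-by-SNPs dosage matrix.
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @return list of class `grm`: `A` (n-by-n), `subject_ids`, `M` (SNPs used),
#'   `n_excluded`.
#' @export
compute_grm <- function(genotypes, maf_min = 0.01) {
  dosage <- if (inherits(genotypes, "genotypes")) genotypes$dosage
            else as.matrix(genotypes)
  ids <- rownames(dosage) %||% sprintf("subj%05d", seq_len(nrow(dosage)))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  if (anyNA(dosage)) {
    for (j in which(colSums(is.na(dosage)) > 0))
      dosage[is.na(dosage[, j]), j] <- 2 * p[j]
  }
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & maf > 0
  if (!any(keep)) stop("all SNPs filtered at maf_min = ", maf_min)
  W <- sweep(dosage[, keep, drop = FALSE], 2, 2 * p[keep])
  W <- sweep(W, 2, sqrt(2 * p[keep] * (1 - p[keep])), `/`)
  M <- sum(keep)
  A <- tcrossprod(W) / M
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, subject_ids = ids, M = M,
                 n_excluded = sum(!keep)), class = "grm")
}

reml_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  df <- as.data.frame(covariates)
  df <- df[setdiff(names(df), "subject_id")]
  X <- stats::model.matrix(~ ., data = df)  # factors one-hot, first level dropped
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  X
}

# restricted log-likelihood pieces in the GRM eigenbasis; lam = eigenvalues,
# yt/Xt = rotated phenotype/design
reml_loglik_parts <- function(theta, lam, yt, Xt) {
  d <- theta[1] * lam + theta[2]
  if (any(d <= 0)) return(NULL)
  W <- 1 / d
  Tm <- crossprod(Xt, Xt * W)
  Rt <- tryCatch(chol(Tm), error = function(e) NULL)
  if (is.null(Rt)) return(NULL)
  beta <- backsolve(Rt, backsolve(Rt, crossprod(Xt, yt * W), transpose = TRUE))
  r <- drop(yt - Xt %*% beta)
  Py <- W * r
  n <- length(yt); k <- ncol(Xt)
  ll <- -0.5 * ((n - k) * log(2 * pi) + sum(log(d)) +
                  2 * sum(log(diag(Rt))) + sum(r * Py))
  list(ll = ll, Py = Py, W = W, Rt = Rt, beta = beta, d = d)
}

# apply the REML projection P to a vector, given W = V^-1 diag and chol(T)
apply_P <- function(v, W, Xt, Rt) {
  Wv <- W * v
  W * v - W * drop(Xt %*% backsolve(Rt, backsolve(Rt, crossprod(Xt, Wv),
                                                  transpose = TRUE)))
}

#' REML variance components on a GRM (SNP-heritability)
#'
#' Fits `y = X beta + g + e` with `V = sigma2_g A + sigma2_e I` by restricted
#' maximum likelihood. Updates are average-information Newton steps with an
#' expectation-maximization fallback whenever a step leaves the parameter
#' space or decreases the restricted likelihood; components are constrained
#' nonnegative. `h2 = sigma2_g / (sigma2_g + sigma2_e)`; its standard error
#' comes from the inverse average-information matrix by the delta method, and
#' the test of `sigma2_g = 0` uses the boundary mixture
#' `0.5 chi2_0 + 0.5 chi2_1` (see [lrt_pvalue()]).
#'
#' @param y phenotype vector.
#' @param covariates covariate table (factors allowed; intercept added) or
#'   `NULL`.
#' @param grm a [compute_grm()] result (or an n-by-n relatedness matrix).
#' @param tol convergence tolerance on the restricted log-likelihood change.
#' @param max_iter maximum REML iterations.
#' @return list of class `varcomp`: `sigma2_g`, `sigma2_e`, `h2`, `se_h2`,
#'   `loglik`, `loglik_null`, `lrt_p`, `converged`, `n_iter`, `n`, `beta`.
#' @export
reml_fit <- function(y, covariates = NULL, grm, tol = 1e-8, max_iter = 100L) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  n <- length(y)
  stopifnot(nrow(A) == n, ncol(A) == n)
  if (n < 30L) stop("need at least 30 subjects for REML")
  X <- reml_design(covariates, n)
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  k <- ncol(Xt)

  vy <- stats::var(stats::lm.fit(X, y)$residuals) * (n - 1) / (n - k)
  floor_v <- 1e-8 * vy
  theta <- c(vy / 2, vy / 2)
  parts <- reml_loglik_parts(theta, lam, yt, Xt)
  if (is.null(parts)) stop("singular V at initialization")
  ll <- parts$ll
  ll_trace <- ll
  converged <- FALSE
  AI <- diag(2)
  for (it in seq_len(max_iter)) {
    Py <- parts$Py; W <- parts$W; Rt <- parts$Rt
    # traces of P V_k via the eigenbasis
    XtW2 <- crossprod(Xt, Xt * (lam * W^2))
    XtW2e <- crossprod(Xt, Xt * W^2)
    Tinv <- chol2inv(Rt)
    tr_PA <- sum(lam * W) - sum(Tinv * XtW2)
    tr_P <- sum(W) - sum(Tinv * XtW2e)
    yPAPy <- sum(lam * Py^2)
    yPPy <- sum(Py^2)
    score <- -0.5 * c(tr_PA - yPAPy, tr_P - yPPy)
    ug <- lam * Py
    Pug <- apply_P(ug, W, Xt, Rt)
    Pue <- apply_P(Py, W, Xt, Rt)
    AI <- 0.5 * rbind(c(sum(ug * Pug), sum(ug * Pue)),
                      c(sum(ug * Pue), sum(Py * Pue)))
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      cand <- pmax(theta + step, floor_v)
      pc <- reml_loglik_parts(cand, lam, yt, Xt)
      if (!is.null(pc) && pc$ll >= ll - 1e-10) {
        theta <- cand; new_ll <- pc$ll; parts <- pc; accepted <- TRUE
      }
    }
    if (!accepted) {  # EM fallback: guaranteed ascent direction
      cand <- pmax(theta + theta^2 / n * c(yPAPy - tr_PA, yPPy - tr_P),
                   floor_v)
      pc <- reml_loglik_parts(cand, lam, yt, Xt)
      if (is.null(pc)) break
      theta <- cand; new_ll <- pc$ll; parts <- pc
    }
    ll_trace <- c(ll_trace, new_ll)
    if (abs(new_ll - ll) < tol * (1 + abs(new_ll))) {
      ll <- new_ll; converged <- TRUE; break
    }
    ll <- new_ll
  }

  s2g <- theta[1]; s2e <- theta[2]
  tot <- s2g + s2e
  h2 <- s2g / tot
  AIinv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  gvec <- c(s2e, -s2g) / tot^2
  se_h2 <- sqrt(max(drop(t(gvec) %*% AIinv %*% gvec), 0))

  # null model sigma2_g = 0: closed-form REML of the linear model
  fit0 <- stats::lm.fit(X, y)
  rss <- sum(fit0$residuals^2)
  s2e0 <- rss / (n - k)
  ll0 <- -0.5 * ((n - k) * (log(2 * pi) + 1 + log(s2e0)) +
                   determinant(crossprod(X), logarithm = TRUE)$modulus[1])
  lrt_p <- lrt_pvalue(max(ll, ll0), ll0)

  structure(list(sigma2_g = s2g, sigma2_e = s2e, h2 = h2, se_h2 = se_h2,
                 loglik = ll, loglik_null = ll0, lrt_p = lrt_p,
                 ll_trace = ll_trace,
                 converged = converged, n_iter = it, n = n,
                 beta = drop(parts$beta)),
            class = "varcomp")
}

#' Boundary likelihood-ratio p-value for a variance component
#'
#' Tests `sigma2_g = 0` on the boundary of the parameter space:
#' `p = 0.5 P(chi2_1 >= 2 (ll_full - ll_null))` for a positive likelihood
#' gain, and 1 otherwise (the `0.5 chi2_0 + 0.5 chi2_1` mixture).
#'
#' @param loglik_full,loglik_null restricted log-likelihoods.
#' @return p-value in (0, 1].
#' @export
lrt_pvalue <- function(loglik_full, loglik_null) {
  if (loglik_full < loglik_null - 1e-6)
    stop("full-model log-likelihood below the null: fits are inconsistent")
  delta <- loglik_full - loglik_null
  if (delta <= 0) return(1)
  0.5 * stats::pchisq(2 * delta, df = 1, lower.tail = FALSE)
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "REML variance components (n = %d)\n  sigma2_g = %.4g, sigma2_e = %.4g\n  h2 = %.3f (se %.3f), LRT p = %.3g\n  converged: %s in %d iterations\n",
    x$n, x$sigma2_g, x$sigma2_e, x$h2, x$se_h2, x$lrt_p,
    x$converged, x$n_iter))
  invisible(x)
}
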