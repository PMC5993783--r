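# independent restricted log-likelihood: dense-matrix formula, no eigen
# shortcuts (used as the grid-search oracle)
reml_ll_dense <- function(s2g, s2e, y, X, A) {
  n <- length(y)
  V <- s2g * A + diag(s2e, n)
  R <- chol(V)
  Vi <- chol2inv(R)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * ((n - ncol(X)) * log(2 * pi) + 2 * sum(log(diag(R))) +
            determinant(XtVX, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

test_that("GRM matches the hand-worked allele-frequency-standardized formula", {
  dosage <- matrix(c(0, 1, 2, 1,
                     2, 2, 1, 0,
                     1, 0, 0, 1), 4, 3)
  g <- compute_grm(dosage, maf_min = 0.01)
  p <- colMeans(dosage) / 2
  Aref <- matrix(0, 4, 4)
  for (j in 1:4) for (k in 1:4)
    Aref[j, k] <- mean((dosage[j, ] - 2 * p) * (dosage[k, ] - 2 * p) /
                         (2 * p * (1 - p)))
  expect_equal(unname(g$A), Aref, tolerance = 1e-12)
  expect_equal(g$M, 3L)
  expect_true(isSymmetric(g$A))
})

test_that("duplicated genomes show relatedness equal to the diagonal", {
  set.seed(51)
  dosage <- matrix(rbinom(20 * 50, 2, 0.3), 20, 50)
  dosage[2, ] <- dosage[1, ]
  g <- compute_grm(dosage)
  expect_equal(g$A[1, 2], g$A[1, 1], tolerance = 1e-12)
  expect_equal(g$A[1, 2], g$A[2, 2], tolerance = 1e-12)
})

test_that("unrelated-panel GRM has the theoretical sampling spread", {
  set.seed(53)
  M <- 2000
  dosage <- matrix(rbinom(500 * M, 2, rep(runif(M, 0.1, 0.5), each = 500)),
                   500, M)
  g <- compute_grm(dosage)
  off <- g$A[upper.tri(g$A)]
  expect_lt(abs(mean(off)), 0.005)
  expect_lt(abs(sd(off) - 1 / sqrt(M)), 0.2 / sqrt(M))
  expect_lt(abs(mean(diag(g$A)) - 1), 0.1)
})

test_that("MAF filtering counts exclusions and errors when nothing is left", {
  dosage <- cbind(rbinom(50, 2, 0.3), c(rep(0, 49), 1))  # second SNP rare
  g <- compute_grm(dosage, maf_min = 0.05)
  expect_equal(g$M, 1L)
  expect_equal(g$n_excluded, 1L)
  expect_error(compute_grm(dosage, maf_min = 0.49), "filtered")
})

sim_h2_data <- function(n, M, h2, seed, k_cov = 2) {
  set.seed(seed)
  maf <- runif(M, 0.1, 0.5)
  dosage <- matrix(rbinom(n * M, 2, rep(maf, each = n)), n, M)
  W <- scale(dosage)
  g <- drop(W %*% rnorm(M)) / sqrt(M)
  g <- if (h2 > 0) g * sqrt(h2) / sd(g) else 0 * g
  covs <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5))
  y <- g + rnorm(n, 0, sqrt(1 - h2)) + 0.02 * covs$age + 0.3 * covs$sex
  list(y = y, covs = covs, grm = compute_grm(dosage))
}

test_that("REML estimate maximizes the dense-formula restricted likelihood (n = 60)", {
  d <- sim_h2_data(60, 300, 0.5, seed = 55)
  fit <- reml_fit(d$y, d$covs, d$grm, tol = 1e-10)
  X <- stats::model.matrix(~ age + sex, d$covs)
  # dense 2-D grid over (h2, total variance)
  h2_grid <- seq(0.01, 0.99, by = 0.02)
  vt_grid <- seq(0.3, 3, by = 0.05)
  best <- c(NA, NA); best_ll <- -Inf
  for (h2 in h2_grid) for (vt in vt_grid) {
    ll <- reml_ll_dense(h2 * vt, (1 - h2) * vt, d$y, X, d$grm$A)
    if (ll > best_ll) { best_ll <- ll; best <- c(h2, vt) }
  }
  expect_lt(abs(fit$h2 - best[1]), 0.02 + 1e-9)          # grid resolution
  tot <- fit$sigma2_g + fit$sigma2_e
  expect_lt(abs(tot - best[2]), 0.05 + 1e-9)
  # and the reported maximum dominates the whole grid
  expect_gte(fit$loglik + 1e-6, best_ll)
  expect_true(fit$converged)
})

test_that("restricted likelihood is non-decreasing over accepted iterations", {
  d <- sim_h2_data(80, 200, 0.4, seed = 57)
  fit <- reml_fit(d$y, d$covs, d$grm)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("estimates are invariant to invertible covariate reparameterization", {
  d <- sim_h2_data(70, 250, 0.4, seed = 59)
  f1 <- reml_fit(d$y, d$covs, d$grm, tol = 1e-10)
  covs2 <- data.frame(a = 2 * d$covs$age + 3 * d$covs$sex - 5,
                      b = d$covs$sex - 0.5)
  f2 <- reml_fit(d$y, covs2, d$grm, tol = 1e-10)
  expect_lt(abs(f1$sigma2_g - f2$sigma2_g), 1e-6)
  expect_lt(abs(f1$sigma2_e - f2$sigma2_e), 1e-6)
  # the restricted likelihood shifts by log|det C| under X -> XC, but the
  # full-vs-null gap (and so the LRT) is invariant
  expect_lt(abs((f1$loglik - f1$loglik_null) -
                  (f2$loglik - f2$loglik_null)), 1e-6)
  expect_lt(abs(f1$lrt_p - f2$lrt_p), 1e-8)
})

test_that("null phenotypes rarely reach LRT significance", {
  hits <- 0
  for (r in 1:60) {
    d <- sim_h2_data(120, 150, 0, seed = 6000 + r)
    fit <- reml_fit(d$y, d$covs, d$grm)
    hits <- hits + (fit$lrt_p < 0.05)
  }
  expect_lte(hits / 60, 0.10)
})

test_that("boundary LRT: limits, the printed-p inversion, monotonicity", {
  expect_equal(lrt_pvalue(10, 10), 1.0)
  expect_equal(lrt_pvalue(10 - 1e-7, 10), 1.0)  # within tolerance, delta <= 0
  expect_error(lrt_pvalue(9, 10), "below the null")
  expect_equal(lrt_pvalue(5.4139, 0), 5e-4, tolerance = 0.01)
  p <- sapply(c(0.5, 1, 2, 4, 8), function(d) lrt_pvalue(d, 0))
  expect_true(all(diff(p) < 0))
})

test_that("varcomp invariants hold on a moderate planted-h2 fit", {
  d <- sim_h2_data(300, 400, 0.6, seed = 61)
  fit <- reml_fit(d$y, d$covs, d$grm)
  expect_gte(fit$h2, 0)
  expect_lte(fit$h2, 1)
  expect_gt(fit$sigma2_g + fit$sigma2_e, 0)
  expect_gt(fit$se_h2, 0)
  expect_gt(fit$lrt_p, 0)
  expect_lte(fit$lrt_p, 1)
})
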