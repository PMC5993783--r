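# closed-form least-squares oracle via normal equations
ols_oracle <- function(y, x, covars = NULL) {
  D <- cbind(1, x, covars)
  b <- solve(crossprod(D), crossprod(D, y))
  r <- y - D %*% b
  df <- length(y) - ncol(D)
  s2 <- sum(r^2) / df
  V <- s2 * solve(crossprod(D))
  list(beta = b[2], se = sqrt(V[2, 2]),
       p = 2 * pt(-abs(b[2] / sqrt(V[2, 2])), df))
}

test_that("identity fit: score equal to dosage gives beta 1 with zero residual", {
  d <- c(0, 0, 1, 1, 2, 2, 1, 0)
  r <- associate_snp(d, d)
  expect_equal(r$beta, 1.0)
  expect_equal(r$p, 0)  # exact nonzero fit: slope present with no noise
})

test_that("worked 8-point set matches the normal-equations oracle to 1e-10", {
  dosage <- c(0, 0, 1, 1, 1, 2, 2, 2)
  score <- c(0.50, 0.52, 0.55, 0.54, 0.56, 0.60, 0.59, 0.61)
  r <- associate_snp(score, dosage)
  o <- ols_oracle(score, dosage)
  expect_equal(r$beta, o$beta, tolerance = 1e-10)
  expect_equal(r$se, o$se, tolerance = 1e-10)
  expect_equal(r$p, o$p, tolerance = 1e-10)
})

test_that("covariate adjustment matches the oracle and rejects collinearity", {
  set.seed(17)
  n <- 60
  covars <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5))
  covars$age_sq <- covars$age^2
  x <- rbinom(n, 2, 0.3)
  y <- 0.1 * x + 0.01 * covars$age + rnorm(n)
  r <- associate_snp(y, x, covars)
  o <- ols_oracle(y, x, as.matrix(covars))
  expect_equal(r$beta, o$beta, tolerance = 1e-10)
  expect_equal(r$se, o$se, tolerance = 1e-10)
  expect_equal(r$n, n)
  bad <- covars; bad$age2 <- 2 * bad$age
  expect_error(associate_snp(y, x, bad), "age2|collinear")
})

test_that("an orthogonal irrelevant covariate leaves beta unchanged", {
  set.seed(19)
  n <- 40
  x <- rbinom(n, 2, 0.4)
  y <- 0.2 * x + rnorm(n)
  z <- qr.resid(qr(cbind(1, x)), rnorm(n))  # orthogonal to intercept + dosage
  r0 <- associate_snp(y, x)
  r1 <- associate_snp(y, x, data.frame(z = z))
  expect_equal(r1$beta, r0$beta, tolerance = 1e-10)
})

test_that("flipping the effect allele negates beta and preserves se and p", {
  set.seed(23)
  n <- 80
  x <- rbinom(n, 2, 0.3)
  y <- 0.15 * x + rnorm(n)
  a <- associate_snp(y, x, effect_allele = "C", other_allele = "T")
  b <- associate_snp(y, 2 - x, effect_allele = "T", other_allele = "C")
  expect_equal(b$beta, -a$beta, tolerance = 1e-10)
  expect_equal(b$se, a$se, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-10)
})

test_that("monomorphic SNPs are flagged, not errors", {
  r <- associate_snp(rnorm(20), rep(2, 20))
  expect_true(r$excluded)
  expect_true(is.na(r$beta))
})

test_that("scan_region equals per-SNP associate_snp and is order-invariant", {
  cd <- tiny_cohorts()
  idx <- which(cd$covariates$cohort == "A")
  geno <- structure(list(subject_ids = cd$genotypes$subject_ids[idx],
                         panel = cd$genotypes$panel,
                         dosage = cd$genotypes$dosage[idx, , drop = FALSE]),
                    class = "genotypes")
  score <- cd$truth$latent_score[idx]
  covs <- cd$covariates[idx, c("age", "age_sq", "sex", paste0("pc", 1:7))]
  tab <- scan_region(score, geno, covs, cohort = "A")
  expect_equal(nrow(tab), nrow(cd$genotypes$panel))
  expect_equal(tab$snp_id, cd$genotypes$panel$snp_id)  # panel position order
  for (j in c(1, 5, 12)) {
    r <- associate_snp(score, geno$dosage[, j], covs,
                       snp_id = tab$snp_id[j])
    expect_equal(tab$beta[j], r$beta, tolerance = 1e-10)
    expect_equal(tab$se[j], r$se, tolerance = 1e-10)
    expect_equal(tab$p[j], r$p, tolerance = 1e-10)
  }
  # permuted SNP columns give identical results after sorting
  perm <- sample(ncol(geno$dosage))
  geno_p <- geno
  geno_p$dosage <- geno$dosage[, perm]
  geno_p$panel <- geno$panel  # panel order defines output order
  tab_p <- scan_region(score, geno_p, covs, cohort = "A")
  expect_equal(tab_p$beta, tab$beta, tolerance = 1e-12)
})

test_that("stratification: age cut boundary, identity rule, empty strata", {
  covs <- data.frame(age = c(10, 16, 20), cohort = "P")
  s <- stratify_subjects(covs, list(type = "age_cut", cut = 16))
  expect_equal(s$age_ge_16, c(2L, 3L))   # 16 years and older
  expect_equal(s$age_lt_16, 1L)
  expect_equal(sum(lengths(s)), 3L)      # partition conservation
  expect_equal(stratify_subjects(covs, "all"), list(all = 1:3))
  covs2 <- data.frame(age = c(20, 30), cohort = "P")
  expect_warning(s2 <- stratify_subjects(covs2, list(type = "age_cut", cut = 16)),
                 "empty stratum")
  expect_named(s2, "age_ge_16")
})

test_that("null association p-values are well calibrated (light check)", {
  set.seed(29)
  p <- replicate(400, {
    x <- rbinom(60, 2, 0.3)
    associate_snp(rnorm(60), x)$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
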