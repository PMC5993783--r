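test_that("dosage allele frequencies recover target MAFs within 3 binomial SEs", {
  panel <- snp_panel(25, seed = 3)
  g <- simulate_genotypes(5000, panel = panel, ld_decay = 0.5, seed = 3)
  freq <- colMeans(g$genotypes$dosage) / 2
  se <- sqrt(panel$maf * (1 - panel$maf) / (2 * 5000))
  expect_true(all(abs(freq - panel$maf) < 3 * se + 1e-12))
  expect_true(all(g$genotypes$dosage >= 0 & g$genotypes$dosage <= 2))
})

test_that("LD structure: independent SNPs, single SNP, and decay with distance", {
  g0 <- simulate_genotypes(5000, panel = snp_panel(15, maf_corr = 0, seed = 5),
                           ld_decay = 0, seed = 5)
  off <- g0$ld[upper.tri(g0$ld)]
  expect_lt(mean(abs(off)), 0.05)

  g1 <- simulate_genotypes(50, panel = snp_panel(1, seed = 2), seed = 2)
  expect_equal(g1$ld, matrix(1, 1, 1, dimnames = list("snp0001", "snp0001")))

  g <- simulate_genotypes(3000, panel = snp_panel(30, seed = 4),
                          ld_decay = 0.9, seed = 4)
  lag_mean <- sapply(1:10, function(l)
    mean(abs(g$ld[cbind(1:(30 - l), (1 + l):30)])))
  expect_true(all(diff(lag_mean) < 0.05))       # decays on average
  expect_lt(lag_mean[10], lag_mean[1])
  ev <- eigen(g$ld, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("generation is bit-for-bit reproducible from (config, seed)", {
  a <- simulate_genotypes(100, panel_size = 8, seed = 11)
  b <- simulate_genotypes(100, panel_size = 8, seed = 11)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  ca <- tiny_cohorts(seed = 11)
  cb <- tiny_cohorts(seed = 11)
  expect_identical(ca$features, cb$features)
  expect_identical(ca$truth$latent_score, cb$truth$latent_score)
})

test_that("invalid generator arguments are rejected with informative messages", {
  expect_error(snp_panel(5, maf_range = c(0, 0.5)), "lower bound 0")
  expect_error(snp_panel(5, maf_range = c(0.05, 0.7)), "upper bound 0.7")
  expect_error(simulate_case_control(5, 5, delta_case = -1), "nonnegative")
  expect_error(simulate_case_control(1, 5), "at least 2")
  panel <- snp_panel(5, seed = 1)
  expect_error(make_truth(tiny_schema(), panel, h2_true = 1.2), "\\[0, 1\\]")
})

test_that("cohort generator honours sizes, covariate contracts and truth record", {
  cd <- tiny_cohorts()
  expect_equal(nrow(cd$features), 210L)
  expect_equal(nrow(cd$covariates), 210L)
  cov <- cd$covariates
  expect_equal(cov$age_sq, cov$age^2)
  expect_true(all(cov$age > 0))
  for (j in paste0("pc", 1:7)) expect_lt(abs(mean(cov[[j]])), 1e-10)
  expect_s3_class(cd$truth, "synthetic_truth")
  expect_equal(length(cd$truth$latent_score), 210L)
  # youngest (last) cohort spans the age-16 cut
  young <- cov$age[cov$cohort == "C"]
  expect_true(any(young < 16) && any(young >= 16))
})

test_that("latent-score variance decomposition matches h2_true at n = 2000", {
  sizes <- c(X = 2000L)
  panel <- snp_panel(12, seed = 9)
  truth <- make_truth(tiny_schema(), panel, h2_true = 0.6, q2_causal = 0.01,
                      seed = 9)
  cd <- simulate_cohorts(sizes, panel = panel, truth = truth,
                         schema = tiny_schema(), n_background = 400L,
                         seed = 9)
  s <- cd$truth$latent_score
  # remove covariate effects, then check the genetic share of what is left
  covs <- cd$covariates[c("age", "sex", paste0("pc", 1:7))]
  r <- stats::resid(stats::lm(s ~ ., data = covs))
  G <- cbind(cd$genotypes$dosage[, truth$causal_index], cd$background)
  r_gen <- stats::lm.fit(cbind(1, G), r)
  v_gen <- 1 - sum(r_gen$residuals^2) / sum((r - mean(r))^2)
  # OLS overfits with 400 predictors at n = 2000; compare against the
  # adjusted share
  v_adj <- 1 - (1 - v_gen) * (2000 - 1) / (2000 - ncol(G) - 1)
  expect_lt(abs(v_adj - 0.6), 0.1)
})

test_that("case/control generator: counts, separation direction, ICV reduction", {
  cc <- simulate_case_control(22, 16, delta_case = 3, schema = tiny_schema(),
                              seed = 13)
  expect_equal(nrow(cc$features), 38L)
  expect_equal(sum(cc$labels), 22L)
  expect_lt(mean(cc$covariates$icv[cc$labels == 1]),
            mean(cc$covariates$icv[cc$labels == 0]))
  # projection onto the true axis separates the groups
  proj <- drop(cc$features %*% cc$truth$w_true)
  expect_equal(auc_mw(proj, cc$labels), 1.0)

  cc0 <- simulate_case_control(22, 16, delta_case = 0, schema = tiny_schema(),
                               seed = 13)
  proj0 <- drop(cc0$features %*% cc0$truth$w_true)
  a0 <- auc_mw(proj0, cc0$labels)
  expect_gt(a0, 0.25)  # exchangeable groups: no real separation
  expect_lt(a0, 0.75)
})

test_that("zero axis leaves features at pure noise level", {
  panel <- snp_panel(8, seed = 21)
  truth <- make_truth(tiny_schema(), panel, seed = 21)
  truth$w_true <- truth$w_true * 0
  cd <- simulate_cohorts(c(A = 150L), panel = panel, truth = truth,
                         schema = tiny_schema(), n_background = 30L,
                         seed = 21)
  # projections onto any fixed axis have variance ~ feature noise only
  v <- var(drop(cd$features %*% rep(1 / sqrt(64), 64)))
  expect_lt(abs(v - 1), 0.3)
})
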