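# Per-cohort association of the neuroanatomical score with SNP dosages.
# The score is the outcome; dosage (alternate-allele count) is the predictor;
# covariates default to age, age squared, sex and 7 ancestry PCs.

default_assoc_covariates <- function() {
  c("age", "age_sq", "sex", paste0("pc", 1:7))
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  X <- as.matrix(as.data.frame(covariates))
  stopifnot(nrow(X) == n)
  storage.mode(X) <- "double"
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)])
    bad <- colnames(X)[drop_idx - 1L]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Associate one SNP dosage with the score
#'
#' Ordinary least squares of the score on dosage plus covariates plus an
#' intercept. The reported `beta` is the per-allele effect of the alternate
#' (effect) allele on the score scale, with its standard error, t statistic,
#' and two-sided p from the t distribution on `n - k - 2` degrees of freedom
#' (k covariates, plus dosage and intercept). SNPs monomorphic in the cohort
#' are flagged (`excluded = TRUE`, NA estimates) rather than erroring so the
#' meta-analysis can pool the remaining cohorts.
#'
#' @param score numeric outcome vector (the projected 0-1 score).
#' @param dosage alternate-allele dosage in `[0, 2]`.
#' @param covariates data frame / matrix of covariates, or `NULL`.
#' @param snp_id,effect_allele,other_allele,cohort annotation carried through.
#' @return one-row `data.frame` (class `assoc_result`): `snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `t_stat`, `p`, `n`,
#'   `cohort`, `excluded`.
#' @export
associate_snp <- function(score, dosage, covariates = NULL,
                          snp_id = "snp", effect_allele = "A",
                          other_allele = "B", cohort = "cohort") {
  n <- length(score)
  stopifnot(length(dosage) == n)
  X <- as_covariate_matrix(covariates, n)
  k <- if (is.null(X)) 0L else ncol(X)
  if (n < k + 3L) stop("too few subjects for the covariate set")
  res <- data.frame(snp_id = snp_id, effect_allele = effect_allele,
                    other_allele = other_allele, beta = NA_real_,
                    se = NA_real_, t_stat = NA_real_, p = NA_real_,
                    n = n, cohort = cohort, excluded = FALSE,
                    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  if (stats::var(dosage) == 0) { res$excluded <- TRUE; return(res) }
  D <- cbind(`(Intercept)` = 1, dosage = dosage, X)
  fit <- stats::lm.fit(D, score)
  df <- n - ncol(D)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(fit$qr))
  # lm.fit pivots; locate the dosage column after pivoting
  jd <- which(fit$qr$pivot == 2L)
  beta <- fit$coefficients["dosage"]
  se <- sqrt(sigma2 * XtXinv[jd, jd])
  tval <- beta / se
  res$beta <- unname(beta); res$se <- se; res$t_stat <- unname(tval)
  res$p <- if (rss <= 1e-25) {  # exact fit: no sampling noise
    as.numeric(beta == 0)
  } else unname(2 * stats::pt(-abs(tval), df))
  res
}

#' Scan all SNPs of a panel against the score
#'
#' One [associate_snp()] per panel SNP, in panel position order. Internally
#' uses a residualization fast path (Frisch-Waugh: score and dosages are
#' projected off the covariates once) that is algebraically identical to the
#' per-SNP OLS.
#'
#' @param score numeric outcome vector.
#' @param genotypes a `genotypes` object (see [simulate_genotypes()]).
#' @param covariates covariate data frame or `NULL`.
#' @param cohort cohort label for the output rows.
#' @return `data.frame` with one `assoc_result` row per SNP.
#' @export
scan_region <- function(score, genotypes, covariates = NULL,
                        cohort = "cohort") {
  panel <- genotypes$panel
  dosage <- genotypes$dosage[, panel$snp_id, drop = FALSE]
  n <- length(score)
  stopifnot(nrow(dosage) == n)
  X <- as_covariate_matrix(covariates, n)
  D0 <- cbind(1, X)
  k <- ncol(D0) - 1L
  qr0 <- qr(D0)
  ry <- qr.resid(qr0, score)
  RD <- qr.resid(qr0, dosage)
  sxx <- colSums(RD^2)
  syy <- sum(ry^2)
  sxy <- drop(crossprod(RD, ry))
  excluded <- apply(dosage, 2, stats::var) == 0
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  df <- n - k - 2L
  rss <- syy - ifelse(sxx > 0, sxy^2 / sxx, 0)
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p[rss <= 1e-25 & !excluded] <- as.numeric(beta[rss <= 1e-25 & !excluded] == 0)
  out <- data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                    pos = panel$pos, effect_allele = panel$alt_allele,
                    other_allele = panel$ref_allele,
                    beta = beta, se = se, t_stat = tval, p = p, n = n,
                    cohort = cohort, excluded = excluded,
                    stringsAsFactors = FALSE)
  out$beta[excluded] <- NA_real_; out$se[excluded] <- NA_real_
  out$t_stat[excluded] <- NA_real_; out$p[excluded] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Partition subjects into analysis strata
#'
#' Default rule splits a named cohort at an age cut (subjects at or above the
#' cut versus below, "16 years and older" keeps 16 in the older stratum);
#' subjects outside the named cohort are untouched by the split. Rule
#' `"all"` returns the identity partition. Strata are disjoint and
#' exhaustive; empty strata are dropped with a warning.
#'
#' @param covariates covariate table with `age` and `cohort` columns.
#' @param rule `"all"`, or a list with `type = "age_cut"`, `cut` (default 16)
#'   and optional `cohort` (restrict the split to one cohort label).
#' @return named list of integer index vectors.
#' @export
stratify_subjects <- function(covariates, rule = list(type = "age_cut",
                                                      cut = 16)) {
  n <- nrow(covariates)
  if (identical(rule, "all") || identical(rule$type, "all"))
    return(list(all = seq_len(n)))
  stopifnot(identical(rule$type, "age_cut"))
  cut <- rule$cut %||% 16
  in_scope <- if (!is.null(rule$cohort))
    covariates$cohort %in% rule$cohort else rep(TRUE, n)
  older <- which(!in_scope | covariates$age >= cut)
  younger <- which(in_scope & covariates$age < cut)
  out <- list(older, younger)
  names(out) <- c(sprintf("age_ge_%g", cut), sprintf("age_lt_%g", cut))
  empty <- lengths(out) == 0L
  if (any(empty)) {
    warning("empty stratum skipped: ", paste(names(out)[empty], collapse = ", "))
    out <- out[!empty]
  }
  out
}
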