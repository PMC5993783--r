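# Inverse-variance-weighted fixed-effects meta-analysis of per-cohort SNP
# effects, candidate-region Bonferroni correction, and leave-one-cohort-out
# sensitivity runs.

harmonize_alleles <- function(results) {
  ref <- results[1, ]
  flip <- rep(FALSE, nrow(results))
  for (i in seq_len(nrow(results))[-1]) {
    r <- results[i, ]
    if (r$effect_allele == ref$effect_allele &&
        r$other_allele == ref$other_allele) next
    if (r$effect_allele == ref$other_allele &&
        r$other_allele == ref$effect_allele) { flip[i] <- TRUE; next }
    stop("allele mismatch without a valid flip for ", ref$snp_id,
         " between cohorts ", ref$cohort, " and ", r$cohort)
  }
  results$beta[flip] <- -results$beta[flip]
  results$effect_allele <- ref$effect_allele
  results$other_allele <- ref$other_allele
  results
}

#' Inverse-variance-weighted fixed-effects meta-analysis of one SNP
#'
#' Pools per-cohort effects with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b)/sum(w)`, `se = 1/sqrt(sum(w))`, `z = beta/se`, two-sided
#' normal p. Cochran's Q and I^2 are reported as heterogeneity diagnostics
#' only (the pooling is fixed-effects throughout). Effect alleles are
#' harmonized before pooling (beta signs flipped where effect/other alleles
#' are swapped); flagged (monomorphic) cohorts are dropped.
#'
#' @param results `data.frame` of `assoc_result` rows for a single SNP.
#' @return one-row `data.frame` of class `meta_result`: `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_meta`, `se_meta`, `z`, `p`, `k`,
#'   `Q`, `i2`.
#' @export
ivw_meta <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    stop("empty result list: nothing to pool")
  if (length(unique(results$snp_id)) != 1L)
    stop("ivw_meta pools a single SNP; got: ",
         paste(unique(results$snp_id), collapse = ", "))
  sid <- results$snp_id[1]
  results <- results[!isTRUE_vec(results$excluded), , drop = FALSE]
  if (nrow(results) == 0L)
    stop("all cohorts flagged/excluded for ", sid)
  results <- harmonize_alleles(results)
  w <- 1 / results$se^2
  beta <- sum(w * results$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  k <- nrow(results)
  Q <- sum(w * (results$beta - beta)^2)
  if (Q < 1e-10 * (1 + sum(w * results$beta^2))) Q <- 0  # numerical residue
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  out <- data.frame(snp_id = results$snp_id[1],
                    effect_allele = results$effect_allele[1],
                    other_allele = results$other_allele[1],
                    beta_meta = beta, se_meta = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)), k = k, Q = Q, i2 = i2,
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Meta-analyze a whole region scan
#'
#' Applies [ivw_meta()] SNP by SNP to a stacked per-cohort summary table and
#' returns one row per SNP, in panel (position) order when `chrom`/`pos`
#' columns are present.
#'
#' @param assoc_table stacked `assoc_result` rows across cohorts.
#' @return `data.frame` of `meta_result` rows (plus `chrom`/`pos` if known).
#' @export
meta_scan <- function(assoc_table) {
  ids <- unique(assoc_table$snp_id)
  rows <- lapply(ids, function(s)
    ivw_meta(assoc_table[assoc_table$snp_id == s, , drop = FALSE]))
  out <- do.call(rbind, rows)
  if (all(c("chrom", "pos") %in% names(assoc_table))) {
    map <- assoc_table[!duplicated(assoc_table$snp_id),
                       c("snp_id", "chrom", "pos")]
    out <- merge(out, map, by = "snp_id", sort = FALSE)
    out <- out[order(out$chrom, out$pos), ]
  }
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Bonferroni correction for the candidate region
#'
#' Family-wise error control over `m` tests treated as independent (the
#' conservative choice for correlated candidate-region SNPs): significance
#' threshold `alpha/m`, and corrected p-values `min(p * m, 1)` for reporting.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (default 110).
#' @param p optional vector of raw p-values to correct.
#' @return list with `threshold` and (when `p` given) `p_adjusted`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 110L, p = NULL) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  out <- list(threshold = alpha / m)
  if (!is.null(p)) out$p_adjusted <- pmin(p * m, 1)
  out
}

#' Leave-one-cohort-out meta-analysis
#'
#' Repeats the IVW pooling of one SNP with each cohort omitted in turn, for
#' sensitivity analysis of which cohort drives the pooled effect.
#'
#' @param results `assoc_result` rows for one SNP across >= 2 cohorts.
#' @return `data.frame` of `meta_result` rows with an `omitted` column.
#' @export
leave_one_cohort_out <- function(results) {
  results <- results[!isTRUE_vec(results$excluded), , drop = FALSE]
  if (nrow(results) < 2L) stop("need at least 2 cohorts to leave one out")
  rows <- lapply(seq_len(nrow(results)), function(i) {
    r <- ivw_meta(results[-i, , drop = FALSE])
    r$omitted <- results$cohort[i]
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
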