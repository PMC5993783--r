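# Plain-text interchange: PLINK bed/bim/fam and dosage tables, GCTA-format
# GRM, PLINK-style summary statistics, serialized score models, fine-mapping
# inputs/outputs, truth records.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a plain-text dosage table
#'
#' Tab-separated subject-by-SNP table, first column `subject_id`.
#'
#' @param genotypes a `genotypes` object.
#' @param path output file.
#' @export
write_dosage_table <- function(genotypes, path) {
  d <- data.frame(subject_id = genotypes$subject_ids,
                  genotypes$dosage, check.names = FALSE)
  write_tsv(d, path)
}

#' Read a plain-text dosage table
#'
#' @param path file written by [write_dosage_table()].
#' @param panel optional [snp_panel()] to attach.
#' @return a `genotypes` object.
#' @export
read_dosage_table <- function(path, panel = NULL) {
  d <- read_tsv(path)
  dosage <- as.matrix(d[, -1, drop = FALSE])
  rownames(dosage) <- d$subject_id
  structure(list(subject_ids = d$subject_id, panel = panel, dosage = dosage),
            class = "genotypes")
}

#' Write genotypes as PLINK bed/bim/fam
#'
#' Dosages are hard-called by rounding to the nearest genotype. The bed file
#' is SNP-major (magic bytes 0x6c 0x1b 0x01); A1 in the bim is the alternate
#' (dosage-counted) allele, so homozygous-alternate codes as 00.
#'
#' @param genotypes a `genotypes` object with a panel.
#' @param prefix path prefix; writes `prefix.bed`, `prefix.bim`, `prefix.fam`.
#' @param phenotype optional numeric phenotype for the fam file (default -9).
#' @export
write_plink <- function(genotypes, prefix, phenotype = NULL) {
  panel <- genotypes$panel
  stopifnot(!is.null(panel))
  n <- length(genotypes$subject_ids)
  geno <- round(genotypes$dosage)
  geno[geno < 0] <- 0; geno[geno > 2] <- 2
  # per-subject 2-bit codes, A1 = alt: 2 alt -> 00, het -> 10, 0 alt -> 11
  code <- matrix(3L, n, ncol(geno))
  code[geno == 2] <- 0L
  code[geno == 1] <- 2L
  code[is.na(geno)] <- 1L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  n_byte <- ceiling(n / 4)
  pad <- n_byte * 4 - n
  for (j in seq_len(ncol(geno))) {
    v <- c(code[, j], rep(0L, pad))
    dim(v) <- c(4, n_byte)
    writeBin(as.raw(v[1, ] + v[2, ] * 4L + v[3, ] * 16L + v[4, ] * 64L), con)
  }
  bim <- data.frame(panel$chrom, panel$snp_id, 0, panel$pos,
                    panel$alt_allele, panel$ref_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(genotypes$subject_ids, genotypes$subject_ids, 0, 0, 0,
                    if (is.null(phenotype)) -9 else phenotype)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write per-cohort or meta summary statistics
#'
#' PLINK-compatible column names: SNP, CHR, POS, A1, A2, BETA, SE, P, N
#' (plus COHORT for per-cohort tables; Q, I2, K for meta tables).
#'
#' @param tab an association or meta-analysis table.
#' @param path output file.
#' @export
write_summary_stats <- function(tab, path) {
  out <- data.frame(SNP = tab$snp_id, stringsAsFactors = FALSE)
  if (!is.null(tab$chrom)) out$CHR <- tab$chrom
  if (!is.null(tab$pos)) out$POS <- tab$pos
  out$A1 <- tab$effect_allele
  out$A2 <- tab$other_allele
  if (!is.null(tab$beta_meta)) {
    out$BETA <- tab$beta_meta; out$SE <- tab$se_meta
    out$P <- tab$p; out$K <- tab$k; out$Q <- tab$Q; out$I2 <- tab$i2
  } else {
    out$BETA <- tab$beta; out$SE <- tab$se; out$P <- tab$p; out$N <- tab$n
    if (!is.null(tab$cohort)) out$COHORT <- tab$cohort
  }
  write_tsv(out, path)
}

#' Read a summary-statistics table
#'
#' @param path file with PLINK-style columns (at least SNP and P).
#' @return `data.frame` with lower-case package column names.
#' @export
read_summary_stats <- function(path) {
  d <- read_tsv(path)
  map <- c(SNP = "snp_id", CHR = "chrom", POS = "pos", A1 = "effect_allele",
           A2 = "other_allele", BETA = "beta", SE = "se", P = "p", N = "n",
           COHORT = "cohort", K = "k", Q = "Q", I2 = "i2")
  names(d) <- ifelse(names(d) %in% names(map), map[names(d)], names(d))
  d
}

#' Serialize a score model to versioned JSON
#'
#' @param model a `score_model`.
#' @param path output file.
#' @export
write_score_model <- function(model, path) {
  obj <- unclass(model)
  obj$obj_trace <- NULL
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized score model
#'
#' @param path file written by [write_score_model()].
#' @return a `score_model`.
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported score-model format version")
  obj$format_version <- NULL
  obj$weights <- stats::setNames(as.numeric(obj$weights), obj$feature_names)
  structure(obj, class = "score_model")
}

#' Write projected scores as two-column text
#'
#' @param subject_ids character ids.
#' @param scores numeric scores.
#' @param path output file.
#' @export
write_scores <- function(subject_ids, scores, path) {
  write_tsv(data.frame(subject_id = subject_ids, score = scores), path)
}

#' Write a GRM in GCTA text format
#'
#' `prefix.grm.gz`: gzipped rows `i j M A_ij` over the lower triangle
#' (diagonal included); `prefix.grm.id`: FID/IID pairs.
#'
#' @param grm a `grm` object.
#' @param prefix output path prefix.
#' @export
write_grm_gcta <- function(grm, prefix) {
  n <- nrow(grm$A)
  ij <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(
    data.frame(ij[, 1], ij[, 2], grm$M, grm$A[ij]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.table(data.frame(grm$subject_ids, grm$subject_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA text-format GRM
#'
#' @param prefix path prefix as in [write_grm_gcta()].
#' @return a `grm` object.
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  A[cbind(tri[[2]], tri[[1]])] <- tri[[4]]
  structure(list(A = A, subject_ids = ids, M = tri[[3]][1], n_excluded = NA),
            class = "grm")
}

#' Write fine-mapping inputs (Z-scores and LD matrix)
#'
#' Mirrors the usual fine-mapping file conventions: a two-column SNP/Z file
#' and a whitespace-delimited m-by-m LD matrix.
#'
#' @param z named Z-score vector.
#' @param ld LD matrix.
#' @param z_path,ld_path output files.
#' @export
write_finemap_inputs <- function(z, ld, z_path, ld_path) {
  write_tsv(data.frame(SNP = names(z), Z = as.numeric(z)), z_path)
  utils::write.table(format(ld, digits = 10), ld_path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(z_path, ld_path))
}

#' Write fine-mapping outputs (PIP table and credible set)
#'
#' @param posterior a `causal_posterior`.
#' @param pip_path,set_path output files.
#' @export
write_finemap_outputs <- function(posterior, pip_path, set_path) {
  write_tsv(data.frame(SNP = names(posterior$pip),
                       PIP = as.numeric(posterior$pip),
                       IN_CREDIBLE_SET = names(posterior$pip) %in%
                         posterior$credible_set), pip_path)
  writeLines(posterior$credible_set, set_path)
  invisible(c(pip_path, set_path))
}

#' Write a truth record as key-value text
#'
#' @param truth a `synthetic_truth`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  kv <- function(k, v) paste0(k, "=", paste(format(v, digits = 17),
                                            collapse = ","))
  lines <- c(kv("causal_snp_id", truth$causal_snp_id),
             kv("causal_index", truth$causal_index),
             kv("beta_causal", truth$beta_causal),
             kv("h2_true", truth$h2_true),
             kv("q2_causal", truth$q2_causal),
             kv("delta_case", truth$delta_case),
             kv("seed", truth$seed),
             kv("w_true", truth$w_true))
  writeLines(lines, path)
  invisible(path)
}
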