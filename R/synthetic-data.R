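# ---- seed substreams -------------------------------------------------------

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows from one top-level integer seed.
#' Independent stages (genotypes, features, covariates, ...) draw from named
#' substreams so that any stage can be regenerated in isolation.
#'
#' @param seed master integer seed.
#' @param name character label of the substream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, fits R's 32-bit integers
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  s <- ((abs(seed) %% m) * 48271) %% m
  as.integer((s + h) %% (m - 1) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- SNP panel -------------------------------------------------------------

#' Construct a candidate-region SNP panel
#'
#' Builds the marker map for a contiguous candidate region. The default
#' emulates a 110-SNP panel spanning a 2 Mb interval of chromosome 7
#' (72-74 Mb, hg19 analog), the hemi-deletion region interrogated by the
#' association scan.
#'
#' @param n_snps number of SNPs (default 110).
#' @param chrom chromosome label.
#' @param start,end 1-based bp bounds of the region.
#' @param maf_range length-2 numeric, minor-allele-frequency bounds in (0, 0.5].
#' @param maf_corr spatial correlation of allele frequencies within an LD
#'   block; SNPs in tight LD co-segregate and therefore have similar
#'   frequencies, so frequencies follow an AR(1) series (restarted at block
#'   boundaries) mapped into `maf_range` rather than being independent.
#' @param block_size SNPs per haplotype block (frequency correlation restarts
#'   at block boundaries, mirroring recombination hotspots).
#' @param seed integer seed.
#' @return a `data.frame` of class `snp_panel` with columns `snp_id`, `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `maf`, plus a `block` column.
#' @export
snp_panel <- function(n_snps = 110L, chrom = "7", start = 72e6, end = 74e6,
                      maf_range = c(0.05, 0.5), maf_corr = 0.999,
                      block_size = 10L, seed = 1L) {
  stopifnot(n_snps >= 1L, end > start, block_size >= 1L)
  check_maf_range(maf_range)
  block <- (seq_len(n_snps) - 1L) %/% block_size + 1L
  with_seed(derive_seed(seed, "panel"), {
    pos <- sort(sample(seq(start, end), n_snps))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    u <- stats::rnorm(n_snps)
    if (n_snps > 1 && maf_corr > 0)
      for (j in 2:n_snps) {
        if (block[j] != block[j - 1]) next  # frequency resets across blocks
        u[j] <- maf_corr * u[j - 1] + sqrt(1 - maf_corr^2) * u[j]
      }
    panel <- data.frame(
      snp_id = sprintf("snp%04d", seq_len(n_snps)),
      chrom = chrom, pos = pos,
      ref_allele = ref, alt_allele = unname(alt),
      maf = maf_range[1] + (maf_range[2] - maf_range[1]) * stats::pnorm(u),
      block = block,
      stringsAsFactors = FALSE
    )
    class(panel) <- c("snp_panel", "data.frame")
    panel
  })
}

check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2L || any(!is.finite(maf_range)))
    stop("maf_range must be two finite numbers")
  if (maf_range[1] <= 0)
    stop("invalid maf_range: lower bound ", maf_range[1], " must be > 0")
  if (maf_range[2] > 0.5)
    stop("invalid maf_range: upper bound ", maf_range[2], " must be <= 0.5")
  if (maf_range[1] > maf_range[2])
    stop("invalid maf_range: lower bound exceeds upper bound")
  invisible(maf_range)
}

# ---- genotypes -------------------------------------------------------------

#' Simulate LD-structured diploid dosages
#'
#' Haplotypes are drawn from a latent Gaussian with AR(1) correlation
#' `ld_decay^|i-j|` within each haplotype block (the chain restarts at block
#' boundaries, so blocks are independent, as across recombination hotspots),
#' thresholded at each SNP's allele-frequency quantile; the dosage is the sum
#' of two independent haplotypes. This yields positive-semidefinite LD by
#' construction: near-complete correlation inside a block when `ld_decay` is
#' close to 1, none across blocks. A single panel-wide AR(1) is the special
#' case `block_size >= panel size`.
#'
#' @param n_subjects number of subjects.
#' @param panel a [snp_panel()]; alternatively `panel_size`/`maf_range` to
#'   build one internally.
#' @param ld_decay AR(1) latent correlation between adjacent SNPs, in `[0, 1)`.
#' @param seed integer seed.
#' @param panel_size,maf_range used only when `panel` is `NULL`.
#' @param subject_ids optional character ids (default `subj00001`, ...).
#' @return list with elements `genotypes` (class `genotypes`: `subject_ids`,
#'   `panel`, `dosage` matrix in `[0, 2]`) and `ld` (empirical SNP-by-SNP
#'   correlation matrix).
#' @export
simulate_genotypes <- function(n_subjects, panel = NULL, ld_decay = 0.999,
                               seed = 1L, panel_size = 110L,
                               maf_range = c(0.05, 0.5), subject_ids = NULL) {
  stopifnot(n_subjects >= 1L, ld_decay >= 0, ld_decay < 1)
  if (is.null(panel))
    panel <- snp_panel(panel_size, maf_range = maf_range, seed = seed)
  m <- nrow(panel)
  block <- panel$block %||% rep(1L, m)
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%05d", seq_len(n_subjects))
  dosage <- with_seed(derive_seed(seed, "genotypes"), {
    thr <- stats::qnorm(panel$maf)  # latent below threshold => alt allele
    hap <- function() {
      z <- matrix(stats::rnorm(n_subjects * m), n_subjects, m)
      if (ld_decay > 0 && m > 1) {
        w <- sqrt(1 - ld_decay^2)
        for (j in 2:m) {
          if (block[j] != block[j - 1]) next  # independent across blocks
          z[, j] <- ld_decay * z[, j - 1] + w * z[, j]
        }
      }
      sweep(z, 2, thr, `<`) * 1
    }
    hap() + hap()
  })
  dimnames(dosage) <- list(subject_ids, panel$snp_id)
  ld <- empirical_ld(dosage)
  geno <- structure(list(subject_ids = subject_ids, panel = panel,
                         dosage = dosage), class = "genotypes")
  list(genotypes = geno, ld = ld)
}

#' Empirical LD (dosage correlation) matrix
#'
#' Monomorphic columns get zero correlation off-diagonal and 1 on the
#' diagonal, so the result is always a valid correlation matrix.
#'
#' @param dosage subjects-by-SNPs dosage matrix.
#' @return symmetric matrix with unit diagonal.
#' @export
empirical_ld <- function(dosage) {
  sds <- apply(dosage, 2, stats::sd)
  ld <- suppressWarnings(stats::cor(dosage))
  ld[!is.finite(ld)] <- 0
  diag(ld) <- 1
  ld[sds == 0, ] <- 0; ld[, sds == 0] <- 0
  diag(ld) <- 1
  (ld + t(ld)) / 2
}

# ---- feature schema & truth ------------------------------------------------

#' Morphometric feature schema
#'
#' The default schema mirrors a vertex-wise surface morphometry table:
#' 3 measures (surface area, surface geometry, sulcal depth) on each of
#' 2 hemispheres at `n_vertices` mesh vertices, plus `n_subcortical`
#' subcortical volumes. With the defaults (5124 vertices, 16 volumes) the
#' predictor count is 3 x 2 x 5124 + 16 = 30,760.
#'
#' @param n_vertices vertices per hemisphere (default 5124).
#' @param n_subcortical subcortical volume count (default 16).
#' @param measures measure labels.
#' @param hemispheres hemisphere labels.
#' @return list of class `feature_schema` with a precomputed `p` and
#'   `feature_names`.
#' @export
feature_schema <- function(n_vertices = 5124L, n_subcortical = 16L,
                           measures = c("area", "geom", "sulc"),
                           hemispheres = c("lh", "rh")) {
  stopifnot(n_vertices >= 1L, n_subcortical >= 0L)
  vert <- as.vector(outer(
    as.vector(outer(measures, hemispheres, paste, sep = "_")),
    sprintf("v%04d", seq_len(n_vertices)), paste, sep = "_"))
  nm <- c(vert, if (n_subcortical > 0) sprintf("subcort_%02d", seq_len(n_subcortical)))
  structure(list(n_vertices = n_vertices, n_subcortical = n_subcortical,
                 measures = measures, hemispheres = hemispheres,
                 p = length(nm), feature_names = nm),
            class = "feature_schema")
}

#' Ground truth for a synthetic experiment
#'
#' Records the planted multivariate disease axis, the causal SNP and its
#' per-allele effect, the SNP-heritability of the latent score, and the
#' case-group shift, so recovery tests can compare estimates to truth.
#'
#' @param schema a [feature_schema()].
#' @param panel a [snp_panel()] (used to pick the causal SNP).
#' @param h2_true SNP-heritability of the latent score in `[0, 1]`.
#' @param q2_causal fraction of latent-score variance explained by the causal
#'   SNP (counted inside `h2_true`); the default 0.01 plants a small effect.
#' @param delta_case case-group shift, in pooled-SD units (see
#'   [simulate_case_control()]).
#' @param axis_density fraction of features with nonzero loading on the
#'   disease axis (default 0.05): morphological reorganization is regionally
#'   concentrated, not uniform over the cortex, so the axis is sparse.
#' @param causal_index column index of the causal SNP (default: middle of the
#'   panel).
#' @param seed integer seed.
#' @return list of class `synthetic_truth`.
#' @export
make_truth <- function(schema, panel, h2_true = 0.8, q2_causal = 0.01,
                       delta_case = 3, axis_density = 0.05,
                       causal_index = NULL, seed = 1L) {
  if (h2_true < 0 || h2_true > 1) stop("h2_true must be in [0, 1]")
  if (q2_causal < 0 || q2_causal > h2_true)
    stop("q2_causal must be in [0, h2_true]")
  stopifnot(axis_density > 0, axis_density <= 1)
  if (is.null(causal_index)) causal_index <- ceiling(nrow(panel) / 2)
  w <- with_seed(derive_seed(seed, "truth_axis"), {
    k <- max(1L, round(axis_density * schema$p))
    v <- numeric(schema$p)
    v[sample(schema$p, k)] <- stats::rnorm(k)
    v
  })
  w <- w / sqrt(sum(w^2))
  maf <- panel$maf[causal_index]
  # per-allele effect so that beta^2 * 2p(1-p) = q2_causal on the unit-variance
  # latent score
  beta <- sqrt(q2_causal / (2 * maf * (1 - maf)))
  structure(list(
    w_true = w,
    causal_snp_id = panel$snp_id[causal_index],
    causal_index = causal_index,
    beta_causal = beta,
    h2_true = h2_true,
    q2_causal = q2_causal,
    delta_case = delta_case,
    seed = seed
  ), class = "synthetic_truth")
}

# ---- multi-cohort generator ------------------------------------------------

default_cohort_sizes <- function() {
  c(ADNI = 184L, HUNT = 653L, NCNG = 325L, TOP = 250L, PING = 451L)
}

#' Simulate multi-cohort imaging-genetics data with planted effects
#'
#' Generates, for a set of cohorts, candidate-region dosages, background
#' dosages (the polygenic term and GRM fodder), a latent quantitative score
#' with the planted causal effect and SNP-heritability, covariates
#' (age, age squared, sex, 7 ancestry PCs, ICV, cohort), and a morphometry
#' matrix carrying the score along the planted axis with additive per-cohort
#' scanner offsets.
#'
#' The latent score decomposes (before covariate effects) into
#' causal + polygenic + residual with variances `q2`, `h2 - q2`, `1 - h2`.
#' Covariate effects (age, sex, PCs) are added on top so the association
#' stage has real confounding to remove. The youngest cohort (last label,
#' PING analog by default) receives a child-to-adult age range so the
#' age-16 stratification is meaningful.
#'
#' @param cohort_sizes named integer vector (default 184/653/325/250/451).
#' @param panel a [snp_panel()] (default: 110-SNP region).
#' @param truth a [make_truth()] record; built from defaults when `NULL`.
#' @param schema a [feature_schema()].
#' @param ld_decay adjacent-SNP latent correlation for the candidate region.
#' @param n_background number of unlinked background SNPs driving the
#'   polygenic term (default 1000).
#' @param axis_snr scale of the score signal on the morphometry axis relative
#'   to unit feature noise (default 3).
#' @param axis_center_frac where the healthy cohorts sit along the
#'   case-control axis, as a fraction of the case shift (default 0.5).
#'   Healthy-population scores on the similarity scale are mid-range, not
#'   piled at the control extreme, so the cohort baseline is centered
#'   between the training groups; 0 would put cohorts exactly at the
#'   control mean.
#' @param cohort_offset_sd SD of the additive per-cohort feature offset.
#' @param seed integer seed.
#' @return list of class `cohort_data`: `genotypes`, `ld`, `background`
#'   (dosage matrix), `features`, `covariates`, `truth` (with the realized
#'   latent score attached as `latent_score`), `cohort_sizes`.
#' @export
simulate_cohorts <- function(cohort_sizes = default_cohort_sizes(),
                             panel = NULL, truth = NULL,
                             schema = feature_schema(), ld_decay = 0.999,
                             n_background = 1000L, axis_snr = 3,
                             axis_center_frac = 0.5, cohort_offset_sd = 0.3,
                             seed = 1L) {
  if (length(cohort_sizes) == 0) stop("cohort_sizes must be nonempty")
  if (is.null(names(cohort_sizes)))
    names(cohort_sizes) <- sprintf("cohort%02d", seq_along(cohort_sizes))
  n <- sum(cohort_sizes)
  if (is.null(panel)) panel <- snp_panel(seed = seed)
  if (is.null(truth)) truth <- make_truth(schema, panel, seed = seed)
  if (truth$h2_true < 0 || truth$h2_true > 1) stop("h2_true must be in [0, 1]")
  stopifnot(length(truth$w_true) == schema$p)

  gsim <- simulate_genotypes(n, panel = panel, ld_decay = ld_decay,
                             seed = derive_seed(seed, "region"))
  geno <- gsim$genotypes
  cohort <- factor(rep(names(cohort_sizes), cohort_sizes),
                   levels = names(cohort_sizes))

  # unlinked background SNPs for the polygenic term / GRM
  bg <- with_seed(derive_seed(seed, "background"), {
    p_bg <- stats::runif(n_background, 0.05, 0.5)
    matrix(stats::rbinom(n * n_background, 2L, rep(p_bg, each = n)),
           n, n_background)
  })
  dimnames(bg) <- list(geno$subject_ids,
                       sprintf("bg%05d", seq_len(n_background)))

  covariates <- with_seed(derive_seed(seed, "covariates"), {
    age <- numeric(n)
    young <- cohort == names(cohort_sizes)[length(cohort_sizes)]
    age[!young] <- stats::runif(sum(!young), 20, 75)
    age[young] <- stats::runif(sum(young), 3, 21)
    sex <- stats::rbinom(n, 1L, 0.5)
    pcs <- matrix(stats::rnorm(n * 7), n, 7)
    pcs <- scale(pcs, center = TRUE, scale = FALSE)
    # ICV is itself strongly heritable; give it a polygenic component from
    # the same background so anything it feeds downstream stays genetic
    icv_h2 <- 0.8
    g_icv <- if (n_background > 0) {
      raw <- drop(scale(bg, center = TRUE, scale = FALSE) %*%
                    stats::rnorm(n_background))
      raw * sqrt(icv_h2) / max(stats::sd(raw), .Machine$double.eps)
    } else numeric(n)
    icv <- 1.45e6 + 1.2e5 * (sex - 0.5) +
      1.3e5 * (g_icv + stats::rnorm(n, 0, sqrt(1 - icv_h2)))
    d <- data.frame(subject_id = geno$subject_ids, age = age, age_sq = age^2,
                    sex = sex, pcs, icv = icv, cohort = cohort,
                    stringsAsFactors = FALSE)
    names(d)[5:11] <- paste0("pc", 1:7)
    d
  })

  score_parts <- with_seed(derive_seed(seed, "score"), {
    x_c <- geno$dosage[, truth$causal_index]
    causal <- truth$beta_causal * (x_c - mean(x_c))
    v_bg <- max(truth$h2_true - truth$q2_causal, 0)
    g <- if (v_bg > 0 && n_background > 0) {
      b <- stats::rnorm(n_background)
      raw <- scale(bg, center = TRUE, scale = FALSE) %*% b
      drop(raw) * sqrt(v_bg) / max(stats::sd(raw), .Machine$double.eps)
    } else numeric(n)
    e <- stats::rnorm(n, 0, sqrt(max(1 - truth$h2_true, 0)))
    cov_eff <- 0.01 * (covariates$age - mean(covariates$age)) +
      0.1 * (covariates$sex - 0.5) +
      as.matrix(covariates[paste0("pc", 1:7)]) %*% rep(0.05, 7)
    causal + g + e + drop(cov_eff)
  })
  s <- drop(score_parts)

  features <- with_seed(derive_seed(seed, "features"), {
    offs <- stats::rnorm(length(cohort_sizes), 0, cohort_offset_sd)
    E <- matrix(stats::rnorm(n * schema$p), n, schema$p)
    # baseline sits axis_center_frac of the case shift along the axis
    # (case shift = delta_case * sqrt(p) on the unit axis, cf.
    # simulate_case_control)
    center <- axis_center_frac * (truth$delta_case %||% 0) * sqrt(schema$p)
    F <- E + outer(axis_snr * s + center, truth$w_true) +
      offs[as.integer(cohort)]
    dimnames(F) <- list(geno$subject_ids, schema$feature_names)
    F
  })

  truth$latent_score <- stats::setNames(s, geno$subject_ids)
  structure(list(genotypes = geno, ld = gsim$ld, background = bg,
                 features = features, covariates = covariates, truth = truth,
                 cohort_sizes = cohort_sizes, schema = schema),
            class = "cohort_data")
}

# ---- case/control training set --------------------------------------------

#' Simulate a case/control morphometry training set
#'
#' Controls are drawn as unit-variance feature noise; the case-group mean is
#' shifted, feature by feature, by `delta_case` pooled SDs modulated by the
#' planted axis rescaled to unit root-mean-square loading. Case ICV is
#' reduced by ~11% relative to controls (the characteristic global brain-size
#' reduction of the syndrome), so the ICV-covariate logic in training is
#' exercised by real signal.
#'
#' @param n_cases,n_controls group sizes (defaults 22 and 16).
#' @param delta_case nonnegative shift in pooled-SD units (default 3).
#' @param truth optional [make_truth()]; its axis is reused so the training
#'   set and the cohorts share the same planted axis.
#' @param schema a [feature_schema()]; ignored when `truth` is given alongside
#'   a matching schema.
#' @param seed integer seed.
#' @return list of class `case_control`: `features`, `labels` (1 = case),
#'   `covariates` (age, sex, icv), `truth`.
#' @export
simulate_case_control <- function(n_cases = 22L, n_controls = 16L,
                                  delta_case = 3, truth = NULL,
                                  schema = feature_schema(), seed = 1L) {
  if (n_cases < 2L || n_controls < 2L)
    stop("need at least 2 subjects per class")
  if (delta_case < 0) stop("delta_case must be nonnegative")
  if (is.null(truth)) {
    panel <- snp_panel(seed = seed)
    truth <- make_truth(schema, panel, delta_case = delta_case, seed = seed)
  }
  p <- length(truth$w_true)
  n <- n_cases + n_controls
  labels <- rep(c(1L, 0L), c(n_cases, n_controls))
  ids <- sprintf("cc%03d", seq_len(n))
  # axis rescaled to RMS loading 1: each feature j is shifted by
  # delta_case * w_rms_j pooled SDs
  w_rms <- truth$w_true * sqrt(p)
  out <- with_seed(derive_seed(seed, "case_control"), {
    X <- matrix(stats::rnorm(n * p), n, p)
    X <- X + outer(labels * delta_case, w_rms)
    age <- stats::runif(n, 18, 55)
    icv <- (1.45e6 - labels * 0.11 * 1.45e6) + stats::rnorm(n, 0, 1e5)
    sex <- stats::rbinom(n, 1L, 0.5)
    list(X = X, age = age, icv = icv, sex = sex)
  })
  dimnames(out$X) <- list(ids, truth$w_true_names %||% feature_names_for(truth, schema))
  covariates <- data.frame(subject_id = ids, age = out$age, sex = out$sex,
                           icv = out$icv, stringsAsFactors = FALSE)
  structure(list(features = out$X, labels = labels, covariates = covariates,
                 truth = truth),
            class = "case_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

feature_names_for <- function(truth, schema) {
  if (length(truth$w_true) == schema$p) schema$feature_names
  else sprintf("f%05d", seq_along(truth$w_true))
}
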