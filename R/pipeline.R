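# Configuration-driven end-to-end runner: simulate (or accept) cohorts ->
# train/apply the neuroanatomical score -> per-cohort candidate-region scans
# -> IVW meta + Bonferroni -> fine-mapping -> enrichment -> heritability.

#' Pipeline configuration
#'
#' All defaults together reproduce the full study-scale experiment from a
#' single seed: five cohorts of 184/653/325/250/451 subjects, a 110-SNP candidate
#' region, a 30,760-feature morphometry schema, a 22-case/16-control training
#' set, a planted causal SNP explaining 1% of the latent score and a
#' polygenic background at SNP-heritability 0.8.
#'
#' @param cohort_sizes named cohort sizes.
#' @param n_snps candidate-region panel size.
#' @param schema a [feature_schema()].
#' @param ld_decay adjacent-SNP latent LD.
#' @param n_background background SNPs for the polygenic term and GRM.
#' @param h2_true,q2_causal,delta_case planted-truth parameters.
#' @param n_cases,n_controls training-set sizes.
#' @param alpha family-wise error rate for the region (default 0.05).
#' @param alpha_mix,n_lambda,cv score-model hyperparameters.
#' @param covariate_names association covariates.
#' @param finemap a [finemap_config()].
#' @param maf_min GRM minor-allele-frequency filter.
#' @param age_cut stratification age (default 16).
#' @param seed master seed.
#' @param out_dir optional output directory for stage files.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_sizes = default_cohort_sizes(),
                       n_snps = 110L, schema = feature_schema(),
                       ld_decay = 0.999, n_background = 1000L,
                       h2_true = 0.8, q2_causal = 0.01, delta_case = 3,
                       n_cases = 22L, n_controls = 16L,
                       alpha = 0.05, alpha_mix = 0.5, n_lambda = 30L,
                       cv = TRUE,
                       covariate_names = default_assoc_covariates(),
                       finemap = finemap_config(), maf_min = 0.01,
                       age_cut = 16, seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(force(expr), error = function(e) {
    structure(list(stage = name, message = conditionMessage(e)),
              class = "stage_error")
  })
  if (inherits(res, "stage_error"))
    report$errors[[name]] <- res$message
  report$stages[[name]] <- res
  report
}

#' Run the full endophenotype association pipeline
#'
#' Stages, in order: train the score model on a simulated case/control set
#' (never overlapping the association cohorts); simulate the cohorts; project
#' scores without recalibration; scan the candidate region per cohort (the
#' youngest cohort additionally split at `age_cut`); IVW meta-analysis with
#' the region Bonferroni threshold; fine-mapping from meta Z-scores and
#' pooled LD; QQ enrichment against a simulated noisy single-ROI reference
#' phenotype on the same genotypes; GRM + REML SNP-heritability of the score.
#' A failing stage is recorded in `report$errors` and does not abort stages
#' that do not depend on it.
#'
#' @param config a [run_config()].
#' @param cohorts optional pre-built `cohort_data` (load mode); simulated
#'   from the config when `NULL`.
#' @return list of class `run_report` with `stages`, `errors`, `config`.
#' @export
run_pipeline <- function(config = run_config(), cohorts = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  report <- list(stages = list(), errors = list(), config = config)

  panel <- snp_panel(config$n_snps, seed = seed)
  truth <- make_truth(config$schema, panel, h2_true = config$h2_true,
                      q2_causal = config$q2_causal,
                      delta_case = config$delta_case, seed = seed)

  report <- run_stage(report, "train", {
    cc <- simulate_case_control(config$n_cases, config$n_controls,
                                config$delta_case, truth = truth,
                                schema = config$schema,
                                seed = derive_seed(seed, "train"))
    fit <- fit_score_model(cc$features, cc$labels, cc$covariates$icv,
                           alpha_mix = config$alpha_mix,
                           n_lambda = config$n_lambda, cv = config$cv)
    list(training = cc, model = fit$model, cv = fit$cv)
  })

  report <- run_stage(report, "simulate", {
    if (!is.null(cohorts)) cohorts
    else simulate_cohorts(config$cohort_sizes, panel = panel, truth = truth,
                          schema = config$schema, ld_decay = config$ld_decay,
                          n_background = config$n_background,
                          seed = derive_seed(seed, "cohorts"))
  })
  cohorts <- report$stages$simulate
  if (inherits(cohorts, "stage_error")) return(finish_report(report))

  report <- run_stage(report, "project", {
    model <- report$stages$train$model
    if (inherits(report$stages$train, "stage_error"))
      stop("score model unavailable: ", report$errors$train)
    project_scores(model, cohorts$features, cohorts$covariates$icv)
  })
  scores <- report$stages$project
  if (inherits(scores, "stage_error")) return(finish_report(report))

  report <- run_stage(report, "assoc", {
    covs <- cohorts$covariates
    groups <- split(seq_len(nrow(covs)), covs$cohort)
    young_label <- names(config$cohort_sizes)[length(config$cohort_sizes)]
    if (young_label %in% names(groups)) {
      idx <- groups[[young_label]]
      strata <- stratify_subjects(covs[idx, ],
                                  list(type = "age_cut", cut = config$age_cut))
      for (s in names(strata))
        groups[[paste0(young_label, "_", s)]] <- idx[strata[[s]]]
    }
    tabs <- lapply(names(groups), function(g) {
      idx <- groups[[g]]
      geno_g <- structure(list(subject_ids = cohorts$genotypes$subject_ids[idx],
                               panel = cohorts$genotypes$panel,
                               dosage = cohorts$genotypes$dosage[idx, ,
                                                                 drop = FALSE]),
                          class = "genotypes")
      scan_region(scores[idx], geno_g,
                  covs[idx, config$covariate_names, drop = FALSE], cohort = g)
    })
    names(tabs) <- names(groups)
    tabs
  })
  assoc_tabs <- report$stages$assoc
  if (inherits(assoc_tabs, "stage_error")) return(finish_report(report))
  base_cohorts <- names(config$cohort_sizes)

  report <- run_stage(report, "meta", {
    stacked <- do.call(rbind, assoc_tabs[base_cohorts])
    meta <- meta_scan(stacked)
    bonf <- bonferroni_threshold(config$alpha, nrow(meta), p = meta$p)
    meta$p_bonferroni <- bonf$p_adjusted
    list(meta = meta, threshold = bonf$threshold,
         top_snp = meta$snp_id[which.min(meta$p)],
         n_significant = sum(meta$p < bonf$threshold, na.rm = TRUE))
  })
  if (inherits(report$stages$meta, "stage_error")) return(finish_report(report))

  report <- run_stage(report, "finemap", {
    z <- meta_z(report$stages$meta$meta, cohorts$genotypes$panel)
    caviar_posterior(z, cohorts$ld, config$finemap)
  })

  report <- run_stage(report, "enrichment", {
    roi <- with_seed(derive_seed(seed, "roi_reference"), {
      icv <- cohorts$covariates$icv
      drop(scale(icv)) + stats::rnorm(length(icv), 0, 3)
    })
    tabs <- lapply(base_cohorts, function(g) {
      idx <- which(cohorts$covariates$cohort == g)
      geno_g <- structure(list(subject_ids = cohorts$genotypes$subject_ids[idx],
                               panel = cohorts$genotypes$panel,
                               dosage = cohorts$genotypes$dosage[idx, ,
                                                                 drop = FALSE]),
                          class = "genotypes")
      scan_region(roi[idx], geno_g,
                  cohorts$covariates[idx, config$covariate_names,
                                     drop = FALSE], cohort = g)
    })
    roi_meta <- meta_scan(do.call(rbind, tabs))
    compare_sets(report$stages$meta$meta$p, roi_meta$p, config$alpha)
  })

  report <- run_stage(report, "heritability", {
    grm <- compute_grm(cbind(cohorts$genotypes$dosage, cohorts$background),
                       config$maf_min)
    covs <- cohorts$covariates[c(config$covariate_names, "cohort")]
    reml_fit(scores, covs, grm)
  })

  finish_report(report)
}

finish_report <- function(report) {
  class(report) <- "run_report"
  cfg <- report$config
  if (!is.null(cfg$out_dir)) write_report_files(report, cfg$out_dir)
  report
}

write_report_files <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- report$stages
  if (!inherits(st$train, "stage_error") && !is.null(st$train))
    write_score_model(st$train$model, file.path(out_dir, "score_model.json"))
  if (!is.null(st$simulate) && !inherits(st$simulate, "stage_error")) {
    write_dosage_table(st$simulate$genotypes,
                       file.path(out_dir, "dosages.tsv"))
    write_tsv(st$simulate$covariates, file.path(out_dir, "covariates.tsv"))
    write_truth(st$simulate$truth, file.path(out_dir, "truth.txt"))
  }
  if (!is.null(st$project) && !inherits(st$project, "stage_error"))
    write_scores(st$simulate$genotypes$subject_ids, st$project,
                 file.path(out_dir, "scores.tsv"))
  if (!is.null(st$assoc) && !inherits(st$assoc, "stage_error"))
    for (g in names(st$assoc))
      write_summary_stats(st$assoc[[g]],
                          file.path(out_dir, paste0("assoc_", g, ".tsv")))
  if (!is.null(st$meta) && !inherits(st$meta, "stage_error"))
    write_summary_stats(st$meta$meta, file.path(out_dir, "meta.tsv"))
  if (!is.null(st$finemap) && !inherits(st$finemap, "stage_error"))
    write_finemap_outputs(st$finemap, file.path(out_dir, "finemap_pip.tsv"),
                          file.path(out_dir, "credible_set.txt"))
  invisible(out_dir)
}

#' Age-stratified pipeline variant
#'
#' Runs the candidate-region association and meta-analysis on the full
#' sample, the subjects at or above `cut_age`, and the subjects below it,
#' reporting the three result blocks side by side. Empty strata are reported
#' and skipped.
#'
#' @param config a [run_config()].
#' @param cut_age stratification age (default from the config).
#' @param cohorts optional pre-built `cohort_data`.
#' @param scores optional precomputed score vector (skips training).
#' @return list of class `stratified_report` with one meta table per block.
#' @export
age_stratified_run <- function(config = run_config(), cut_age = NULL,
                               cohorts = NULL, scores = NULL) {
  stopifnot(inherits(config, "run_config"))
  cut_age <- cut_age %||% config$age_cut
  if (cut_age <= 0) stop("cut_age must be positive")
  if (is.null(cohorts))
    cohorts <- simulate_cohorts(config$cohort_sizes,
                                panel = snp_panel(config$n_snps,
                                                  seed = config$seed),
                                schema = config$schema,
                                ld_decay = config$ld_decay,
                                n_background = config$n_background,
                                seed = derive_seed(config$seed, "cohorts"))
  if (is.null(scores)) scores <- cohorts$truth$latent_score
  covs <- cohorts$covariates
  blocks <- list(full = seq_len(nrow(covs)),
                 older = which(covs$age >= cut_age),
                 younger = which(covs$age < cut_age))
  out <- list()
  for (b in names(blocks)) {
    idx <- blocks[[b]]
    if (length(idx) == 0L) { out[[b]] <- "empty stratum: skipped"; next }
    tabs <- lapply(split(idx, droplevels(factor(covs$cohort[idx]))),
                   function(ii) {
      if (length(ii) < length(config$covariate_names) + 3L) return(NULL)
      geno_g <- structure(list(subject_ids = cohorts$genotypes$subject_ids[ii],
                               panel = cohorts$genotypes$panel,
                               dosage = cohorts$genotypes$dosage[ii, ,
                                                                 drop = FALSE]),
                          class = "genotypes")
      scan_region(scores[ii], geno_g,
                  covs[ii, config$covariate_names, drop = FALSE],
                  cohort = covs$cohort[ii[1]])
    })
    tabs <- tabs[!vapply(tabs, is.null, TRUE)]
    out[[b]] <- meta_scan(do.call(rbind, tabs))
  }
  structure(list(blocks = out, cut_age = cut_age), class = "stratified_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", length(x$stages), "stages,",
      length(x$errors), "errors\n")
  if (!is.null(x$stages$meta) && !inherits(x$stages$meta, "stage_error"))
    cat("  top SNP:", x$stages$meta$top_snp, "| significant after Bonferroni:",
        x$stages$meta$n_significant, "\n")
  if (!is.null(x$stages$heritability) &&
      !inherits(x$stages$heritability, "stage_error"))
    cat(sprintf("  h2 = %.3f (se %.3f)\n", x$stages$heritability$h2,
                x$stages$heritability$se_h2))
  for (e in names(x$errors)) cat("  stage", e, "failed:", x$errors[[e]], "\n")
  invisible(x)
}
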