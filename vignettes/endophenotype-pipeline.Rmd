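---
title: "Multivariate neuroanatomical endophenotypes for candidate-region genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate neuroanatomical endophenotypes for candidate-region genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoscore)
```

## The problem this package addresses

Imaging-genetics studies usually associate genetic variants with
landmark-defined regions of interest (a hippocampal volume, a mean cortical
thickness). Region averages blur genetically coherent signal that is spread
across the cortex and mix in variance from genetically unrelated neighbors.
An alternative is to *learn* the phenotype: train a discriminative model on a
clinical population with a known genetic lesion and a large, reproducible
neuroanatomical signature, then project its decision score — a single
quantitative *endophenotype* — onto large healthy cohorts and run the
genetics on that score.

`endoscore` implements this strategy end to end for a candidate-region
setting modeled on the 7q11.23 hemi-deletion syndrome (Williams Syndrome):

1. **Score model** (`fit_score_model`, `project_scores`): an elastic-net
   penalized logistic discriminant of case status on ~30,760 vertex-wise
   morphometric predictors, with intracranial volume (ICV) as an unpenalized
   covariate so head size cannot drive the classification. Scores are
   sigmoid-transformed, hence in (0, 1).
2. **Association** (`associate_snp`, `scan_region`): per-cohort ordinary
   least squares of the score on each candidate-region SNP dosage,
   controlling age, age squared, sex and seven ancestry PCs.
3. **Meta-analysis** (`ivw_meta`, `meta_scan`): fixed-effects
   inverse-variance-weighted pooling across cohorts, with Cochran's Q and
   I^2 as diagnostics and a Bonferroni threshold of `alpha / m` over the `m`
   region SNPs (0.05/110 = 4.5e-4 at the defaults).
4. **Fine-mapping** (`caviar_posterior`): exhaustive posterior over causal
   configurations of at most K SNPs given the meta Z-scores and the LD
   matrix, per-SNP inclusion probabilities (PIPs) and a rho-credible set.
5. **Enrichment** (`qq_envelope`, `compare_sets`): quantile-quantile
   comparison of the candidate-region p-values against a reference set, with
   Beta order-statistic envelopes.
6. **Heritability** (`compute_grm`, `reml_fit`): GCTA-style genetic
   relationship matrix and average-information REML variance components for
   the SNP-heritability of the score.
7. **Pipeline** (`run_pipeline`, `age_stratified_run`): one-seed,
   configuration-driven runs of the whole flow, including the age-16
   stratification of the youngest cohort and leave-one-cohort-out
   sensitivity pooling.

No real cohort is shipped or downloaded; the `synthetic_data` module
generates multi-cohort data with the statistical structure the analysis
assumes, with recorded ground truth for recovery tests.

## The models

### Penalized logistic score

With standardized features `x`, labels `y` in {0,1}, standardized ICV `v`,
the model minimizes

    (1/n) sum_i [ log(1 + exp(eta_i)) - y_i eta_i ]
      + lambda * ( alpha ||w||_1 + (1 - alpha)/2 ||w||_2^2 ),
    eta_i = b0 + b_icv v_i + x_i' w,

penalizing only `w`. The optimizer is monotone FISTA (proximal gradient with
Nesterov acceleration, backtracking line search, and a descent safeguard:
an accelerated step that would increase the objective is replaced by a plain
descent step with momentum restart), with the inner loop compiled via
RcppArmadillo and a glmnet-style active-set/KKT screen for p >> n problems.
Convergence is declared when the relative objective change falls below
`tol = 1e-8` (default `max_iter` 10,000); the objective trace is stored and
asserted non-increasing in the tests.

The penalty strength is selected by leave-one-out cross-validated AUC over a
30-value log-spaced grid from the data-derived `lambda_max` down two decades
when p >= n (four otherwise, the glmnet convention), ties resolved toward
the larger (more parsimonious) lambda. Every fold restandardizes from its 37
training rows, so the held-out subject never leaks into the scaling. AUC is
the normalized Mann-Whitney U of case versus control scores.

At projection time the trained ICV coefficient *is* applied (with the
training standardization): the score must be computable subject by subject
on new cohorts, and dropping a fitted term would change the discriminant.
This was a genuinely open design point; it is recorded here as the package's
choice.

### Association and meta-analysis

The score is the regression *outcome* and dosage the predictor. A per-allele
effect on the 0-1 score scale (e.g. 0.018 per allele) is only interpretable
in that direction, so the package fixes it even though such analyses are
sometimes described with the roles reversed. Monomorphic-in-cohort SNPs are
flagged and dropped from pooling rather than erroring, so the remaining
cohorts still meta-analyze. Fixed effects only: candidate-region pooling
over five cohorts has too few studies for a stable random-effects variance,
and the heterogeneity statistics are reported for diagnosis, not modeling.

### Fine-mapping posterior

For configuration `c` (the set of causal SNPs, |c| <= K) and LD matrix `S`,

    z | c ~ MVN(0, S + sigma^2 S diag(c) S),

with prior `gamma^|c| (1-gamma)^(m-|c|)`. Because
`S diag(c) S = S[,c] S[c,]` has rank |c|, one Cholesky of `S` plus
determinant-lemma/Woodbury identities give every configuration's likelihood
in O(|c|^3); the tests verify exact agreement (1e-10) with a brute-force
dense enumeration. Defaults K = 2, gamma = 0.01, ncp_sigma = 5.2,
rho = 0.95 — the conventional values for this posterior family. `S` is
regularized by `eps I` with `eps = max(0, 1e-6 - lambda_min)`; `eps` is
recorded in the output. The credible set is grown greedily by PIP (ties to
the smaller position) until the configurations fully contained in the set
carry mass rho.

### GREML heritability

The GRM uses the allele-frequency-standardized estimator
`A_jk = (1/M) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2p_i(1-p_i))`. REML on
`V = sigma2_g A + sigma2_e I` works in the GRM eigenbasis, so each iteration
is O(n k^2) after one eigendecomposition. Updates are average-information
Newton steps; a step that leaves the nonnegative orthant or decreases the
restricted likelihood falls back to the EM update, which is an ascent step.
`se(h2)` comes from the inverse AI matrix by the delta method, and the test
of `sigma2_g = 0` uses the boundary mixture `0.5 chi2_0 + 0.5 chi2_1`. The
restricted likelihood is parameterization-dependent through
`log|X' V^-1 X|`; estimates and the LRT are invariant to invertible
reparameterizations of X (asserted in the tests).

### QQ enrichment

Expected null quantiles use the plotting position `i/(n+1)`; envelopes come
from Beta(i, n-i+1) quantiles. The tail-shift statistic is the mean
difference of the top decile of paired -log10 quantiles. The enrichment
*flag* compares the top-decile points against an envelope made simultaneous
over those monitored points (pointwise level `alpha/n_tail`, a union bound):
a pointwise 95% envelope would fire on >10% of null panels when any of 11
tail points may exceed it, while the union bound keeps the null flag rate
at or below alpha (measured ~1-2%).

## What the synthetic cohorts emulate

The generator reproduces the statistical skeleton of a five-cohort
imaging-genetics study: cohort sizes 184/653/325/250/451 (total 1863); a
110-SNP candidate panel on a 2 Mb chromosome-7 interval; a 30,760-feature
morphometry schema (3 measures x 2 hemispheres x 5124 vertices + 16
subcortical volumes); a latent quantitative score with a planted causal SNP
(1% of score variance by default), a polygenic background scaled to
SNP-heritability 0.8, and age/sex/ancestry confounding; additive per-cohort
scanner offsets on the features (the reason the analysis meta-analyzes
instead of pooling); and a separate 22-case/16-control training set whose
case group is shifted along the planted axis with an ~11% ICV reduction.

Deliberate design choices, and why:

- **LD as haplotype blocks.** Haplotypes come from a latent Gaussian AR(1)
  thresholded at the allele-frequency quantile, with the chain (and the
  allele-frequency series) restarting every `block_size = 10` SNPs:
  near-complete LD within a block (adjacent dosage r^2 ~ 0.94), none
  across. That is the standard picture of a low-recombination candidate
  region — tight blocks bounded by recombination hotspots — and it is what
  makes "the top SNP is the causal variant or a strong proxy" a
  well-defined success criterion. A panel-wide AR(1) is available as the
  `block_size >= m` special case. Two points are easy to miss with
  threshold models: binary thresholding attenuates latent correlation, and
  two SNPs with different allele frequencies cannot reach r^2 = 1, so
  strong dosage LD requires co-segregating (spatially correlated) MAFs —
  the panel draws them that way within blocks.
- **Sparse disease axis.** The planted axis loads on 5% of features
  (`axis_density`): morphological reorganization is regionally
  concentrated, not uniform over the cortex. The case-group shift is
  applied per feature as `delta_case` pooled-SDs scaled by the RMS-1 axis,
  which makes the two groups separable the way a hemideletion syndrome
  with a gross neuroanatomical signature is — a training AUC of 100% is the
  expected outcome at `delta_case = 3`, not a lucky draw. (A unit-norm
  Mahalanobis shift of 3 would cap the attainable AUC near 98% and would
  not emulate the clinical separation this design presumes.)
- **Healthy cohorts sit mid-axis.** Cohort morphometry is centered halfway
  along the case-control axis (`axis_center_frac = 0.5`). Healthy subjects
  score mid-range on the 0-1 similarity scale in this design (reported
  population mean 0.6, SD ~0.1); anchoring cohorts at the control extreme
  would saturate the sigmoid and crush the score's variance.
- **ICV is heritable.** The trained ICV coefficient is applied at
  projection (see above), so whatever drives cohort ICV flows into the
  score. Head size is one of the most heritable human traits (twin and
  SNP-based estimates ~0.8), so cohort ICV gets a polygenic component from
  the same background SNPs (`icv_h2 = 0.8`). With a purely environmental
  ICV the projected score's heritability would be mostly destroyed by
  construction — an artifact of the generator, not a property of the
  design.
- **Latent score as the association phenotype in recovery experiments.**
  The causal SNP explains 1% of the *latent* score by construction;
  projecting through trained weights attenuates that share by the
  morphometry noise. The recovery and calibration suites therefore use the
  recorded latent score, so "1% variance explained" means what it says;
  the pipeline itself always projects through the trained model.
- **One seed, named substreams.** Every stage draws from
  `derive_seed(seed, stage_name)`, so regenerating one stage never
  perturbs another and whole runs are bit-reproducible.

What the generator does *not* emulate: spatial autocorrelation between
neighboring vertices, non-Gaussian feature noise, imputation-quality (INFO)
variation across SNPs, ancestry stratification that correlates PCs with
allele frequencies, and relatedness between subjects. Passing tests say the
estimators behave correctly under the assumed structure — not that real
morphometry satisfies it.

## Numerical choices and problem sizes

- FISTA tolerance 1e-8 (relative objective change), max 10,000 iterations;
  initial step from an 8-iteration power estimate of the spectral norm,
  corrected downward by backtracking only.
- REML tolerance 1e-8 on the restricted log-likelihood change; variance
  floor 1e-8 times the phenotypic variance; at most 100 iterations.
- LD regularization and posterior normalization as above; configuration
  enumeration is capped (default 2e5) and errors with advice rather than
  thrashing.
- Zero-variance features are retained with zero weight and excluded from
  standardization; monomorphic SNPs are flagged; empty strata are skipped
  with a warning.
- The test suite exercises the full-scale pieces where the claim depends
  on scale (the 38 x 30,760 training fit; n = 1863 association scans;
  n = 1000 REML) and scales the rest down (reduced vertex counts,
  30-50-SNP panels, 200-500 background SNPs). These sizes are the package's
  own choices for routine verification; the generator accepts the full
  sizes everywhere.

## Known limitations

- Fine-mapping is exhaustive enumeration; K > 2 over 110 SNPs exceeds the
  default cap by design. Stochastic-search fine-mapping is out of scope.
- Single-component GREML only; no LD-score regression, no bivariate REML.
- The enrichment reference arm is simulated (a noisy single-ROI phenotype
  on the same genotypes); comparisons against real consortium summary
  statistics would need their files, not shipped here.
- The Bonferroni correction deliberately treats the 110 correlated tests as
  independent (conservative); no effective-number correction is applied.
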