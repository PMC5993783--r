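# endoscore

Candidate-region genetics on a learned neuroanatomical endophenotype.

Region-of-interest phenotypes (a hippocampal volume, an average thickness)
discard the distributed, covaried morphological signal that genetic
perturbations of neurodevelopment actually produce. `endoscore` implements
the alternative: train a penalized logistic discriminant on a clinical
population with a known genetic lesion and a gross neuroanatomical
signature (modeled here on the 7q11.23 hemi-deletion syndrome), project its
0-1 decision score onto large healthy cohorts as a single quantitative
endophenotype, and run the candidate-region genetics on that score. The
package is for statistical geneticists and imaging-genetics methodologists
who want the full pipeline — scoring, association, meta-analysis,
fine-mapping, enrichment, heritability — as tested, reusable functions that
work on synthetic cohorts with no data access.

## The model at the core

The score model minimizes, over feature weights `w` with unpenalized
intercept and intracranial-volume (ICV) coefficient,

    (1/n) Σᵢ [log(1 + e^ηᵢ) − yᵢ ηᵢ] + λ (α‖w‖₁ + (1−α)/2 ‖w‖₂²),
    ηᵢ = β₀ + β_icv·ICVᵢ + xᵢᵀw,      score = σ(η) ∈ (0, 1),

fit by monotone FISTA with λ selected by leave-one-out cross-validated AUC.
Downstream, for each candidate SNP: per-cohort OLS of the score on dosage
(age, age², sex, 7 ancestry PCs as covariates), inverse-variance-weighted
fixed-effects pooling (`β̂ = Σwᵢβᵢ/Σwᵢ`, `wᵢ = 1/seᵢ²`) with a Bonferroni
threshold `α/m`; a causal-configuration posterior
`z | c ~ MVN(0, Σ + σ²·Σ diag(c) Σ)` with per-SNP inclusion probabilities
and a ρ-credible set; Beta order-statistic QQ envelopes for local
enrichment; and GREML SNP-heritability (`V = σ²g·A + σ²e·I`, AI-REML with
EM fallback) with a `0.5χ²₀ + 0.5χ²₁` boundary test.

## Worked example

A reduced-size end-to-end run (full cohort sizes, 110-SNP region, 736
morphometric features instead of 30,760 so it finishes in about a minute):

```r
library(endoscore)

cfg <- run_config(cohort_sizes = c(ADNI = 184, HUNT = 653, NCNG = 325,
                                   TOP = 250, PING = 451),
                  schema = feature_schema(n_vertices = 120),
                  n_background = 500, n_lambda = 8, seed = 2026)
rep <- run_pipeline(cfg)
print(rep)
#> Pipeline run: 8 stages, 0 errors
#>   top SNP: snp0056 | significant after Bonferroni: 1
#>   h2 = 0.790 (se 0.014)

m <- rep$stages$meta$meta
m[which.min(m$p), c("snp_id", "beta_meta", "se_meta", "z", "p", "p_bonferroni")]
#>   snp_id  beta_meta     se_meta        z            p p_bonferroni
#>  snp0056 0.02652794 0.007235466 3.666377 0.0002460114   0.02706126

rep$stages$simulate$truth$causal_snp_id
#> [1] "snp0055"
print(rep$stages$heritability)
#> REML variance components (n = 1863)
#>   sigma2_g = 0.02437, sigma2_e = 0.006487
#>   h2 = 0.790 (se 0.014), LRT p = 1.1e-304
print(rep$stages$enrichment)
#> QQ comparison over 110 quantiles
#>   tail shift (top 11 quantiles): 2.318 in -log10(p)
#>   enrichment flag: TRUE (8/11 tail points above the 95% envelope)
```

Reading the output: the training stage reached a leave-one-out AUC of 1.0
and the projected scores sit mid-range (mean 0.46, SD 0.18). The top meta
SNP, `snp0056`, is the immediate LD-block mate (r² ≥ 0.8) of the planted
causal SNP `snp0055`, passes the region Bonferroni threshold
(0.05/110 = 4.5e-4; corrected p = 0.027), and the score recovers the
planted SNP-heritability of 0.8 as ĥ² = 0.79. The candidate-region
p-values are strongly enriched relative to the simulated single-ROI
reference arm (tail shift 2.3 decades of p).

The planted causal effect is deliberately small (1% of score variance), so
at these sample sizes single runs sit near the edge of power — the same
regime the design is meant for; the recovery rates across hundreds of
replicates are what the acceptance suite checks.

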