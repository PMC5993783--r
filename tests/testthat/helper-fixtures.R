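# Small fixtures built in code; kept tiny so unit tests stay fast.

tiny_schema <- function(n_vertices = 10L, n_subcortical = 4L) {
  feature_schema(n_vertices = n_vertices, n_subcortical = n_subcortical)
}

tiny_cohorts <- function(sizes = c(A = 60L, B = 80L, C = 70L), n_snps = 12L,
                         seed = 7L, ...) {
  panel <- snp_panel(n_snps, seed = seed)
  simulate_cohorts(sizes, panel = panel,
                   truth = make_truth(tiny_schema(), panel, seed = seed, ...),
                   schema = tiny_schema(), n_background = 50L, seed = seed)
}

# independent pair-counting AUC (ties counted half)
auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  ok <- 0
  for (a in s1) for (b in s0) ok <- ok + (a > b) + 0.5 * (a == b)
  ok / (length(s1) * length(s0))
}

# independent multivariate-normal log-density via full Cholesky solve
logdmvnorm <- function(z, S) {
  R <- chol(S)
  u <- backsolve(R, z, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(u^2))
}
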