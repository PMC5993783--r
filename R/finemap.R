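# Fine-mapping of the candidate region: posterior over causal configurations
# given region Z-scores and LD, per-SNP inclusion probabilities (PIPs) and a
# rho-credible causal set.
#
# Model: with configuration c (a 0/1 vector of causal SNPs) and LD matrix S,
#   z | c ~ MVN(0, S + ncp_sigma^2 * S diag(c) S).
# Because S diag(c) S = S[, c] S[c, ] has rank |c|, the likelihood of every
# configuration follows from one Cholesky of S via low-rank determinant and
# Woodbury identities; each configuration then costs O(|c|^3).

#' Fine-mapping configuration
#'
#' @param max_causal maximum number of causal SNPs per configuration (K).
#' @param gamma per-SNP prior causal probability.
#' @param ncp_sigma prior scale of the causal non-centrality.
#' @param rho credible-set mass.
#' @param max_config cap on the number of enumerated configurations.
#' @return list of class `finemap_config`.
#' @export
finemap_config <- function(max_causal = 2L, gamma = 0.01, ncp_sigma = 5.2,
                           rho = 0.95, max_config = 2e5) {
  stopifnot(max_causal >= 1L, gamma > 0, gamma < 1, ncp_sigma > 0,
            rho > 0, rho < 1)
  structure(list(max_causal = as.integer(max_causal), gamma = gamma,
                 ncp_sigma = ncp_sigma, rho = rho, max_config = max_config),
            class = "finemap_config")
}

#' Z-scores from meta-analysis results
#'
#' `z_j = beta_meta_j / se_meta_j`, ordered by panel position.
#'
#' @param meta_table `meta_result` rows covering every panel SNP.
#' @param panel a [snp_panel()].
#' @return named numeric vector in panel order.
#' @export
meta_z <- function(meta_table, panel) {
  miss <- setdiff(panel$snp_id, meta_table$snp_id)
  if (length(miss))
    stop("missing meta results for SNP(s): ", paste(miss, collapse = ", "))
  idx <- match(panel$snp_id, meta_table$snp_id)
  stats::setNames(meta_table$beta_meta[idx] / meta_table$se_meta[idx],
                  panel$snp_id)
}

enumerate_configs <- function(m, K, max_config) {
  n_cfg <- sum(vapply(0:K, function(j) choose(m, j), 0))
  if (n_cfg > max_config)
    stop("configuration enumeration too large (", format(n_cfg),
         " > ", format(max_config),
         "); lower max_causal or the panel size")
  cfgs <- list(integer(0))
  for (j in seq_len(K))
    cfgs <- c(cfgs, utils::combn(m, j, simplify = FALSE))
  cfgs
}

#' Posterior over causal configurations (exhaustive enumeration)
#'
#' Enumerates all configurations of at most `max_causal` causal SNPs
#' (including the null configuration), scores each by the multivariate-normal
#' likelihood of the observed Z-scores under LD-spread non-centrality, applies
#' the independent Bernoulli(`gamma`) prior, and normalizes. Reports per-SNP
#' inclusion probabilities and the `rho`-credible set. The LD matrix is
#' regularized to be positive definite by adding `eps * I` with
#' `eps = max(0, 1e-6 - lambda_min)`; `eps` is recorded in the output.
#'
#' @param z named Z-score vector in panel order.
#' @param ld SNP-by-SNP LD (correlation) matrix.
#' @param cfg a [finemap_config()].
#' @return list of class `causal_posterior`: `configs` (data frame with
#'   configuration members, log-likelihood, posterior), `pip`,
#'   `credible_set`, `top_snp`, `null_posterior`, `epsilon`, `cfg`.
#' @export
caviar_posterior <- function(z, ld, cfg = finemap_config()) {
  m <- length(z)
  stopifnot(nrow(ld) == m, ncol(ld) == m)
  snps <- names(z) %||% sprintf("snp%04d", seq_len(m))
  ev_min <- min(eigen(ld, symmetric = TRUE, only.values = TRUE)$values)
  eps <- max(0, 1e-6 - ev_min)
  S <- ld + diag(eps, m)
  R <- chol(S)
  logdetS <- 2 * sum(log(diag(R)))
  Sinv_z <- backsolve(R, backsolve(R, z, transpose = TRUE))
  q0 <- sum(z * Sinv_z)
  s2 <- cfg$ncp_sigma^2
  cfgs <- enumerate_configs(m, cfg$max_causal, cfg$max_config)
  lg <- log(cfg$gamma); l1g <- log(1 - cfg$gamma)
  loglik <- vapply(cfgs, function(cset) {
    j <- length(cset)
    if (j == 0L)
      return(-0.5 * (m * log(2 * pi) + logdetS + q0))
    # covariance S + s2 * S[,c] S[c,]; determinant lemma + Woodbury, using
    # S^-1 S[,c] = I[,c]
    B <- diag(1 / s2, j) + S[cset, cset, drop = FALSE]
    Rb <- chol(B)
    logdet <- logdetS + 2 * sum(log(diag(Rb))) + j * log(s2)
    u <- z[cset]
    corr <- sum(backsolve(Rb, u, transpose = TRUE)^2)
    -0.5 * (m * log(2 * pi) + logdet + (q0 - corr))
  }, 0)
  logprior <- vapply(cfgs, function(cset)
    length(cset) * lg + (m - length(cset)) * l1g, 0)
  lp <- loglik + logprior
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  pip <- numeric(m)
  for (i in seq_along(cfgs)) pip[cfgs[[i]]] <- pip[cfgs[[i]]] + post[i]
  names(pip) <- snps
  configs <- data.frame(
    config = vapply(cfgs, function(cset)
      if (length(cset)) paste(snps[cset], collapse = ",") else "(null)", ""),
    size = lengths(cfgs), loglik = loglik, logprior = logprior,
    posterior = post, stringsAsFactors = FALSE)
  out <- structure(list(configs = configs, config_members = cfgs, pip = pip,
                        null_posterior = post[1],
                        top_snp = snps[which.max(pip)], epsilon = eps,
                        snp_ids = snps, cfg = cfg),
                   class = "causal_posterior")
  out$credible_set <- credible_set(out, cfg$rho)
  out
}

#' rho-credible causal set
#'
#' Greedy by PIP (ties broken toward the smaller panel position): the
#' smallest SNP set whose contained configurations (the null configuration
#' counts as contained in any set) accumulate at least `rho` posterior mass.
#'
#' @param posterior a `causal_posterior`.
#' @param rho target posterior mass in (0, 1).
#' @return character vector of SNP ids.
#' @export
credible_set <- function(posterior, rho = 0.95) {
  stopifnot(inherits(posterior, "causal_posterior"), rho > 0, rho < 1)
  m <- length(posterior$pip)
  ord <- order(-posterior$pip, seq_len(m))  # tie-break: earlier position
  post <- posterior$configs$posterior
  members <- posterior$config_members
  pos_in_ord <- integer(m); pos_in_ord[ord] <- seq_len(m)
  # rank at which each configuration becomes fully contained in the prefix
  rank_in <- vapply(members, function(cset)
    if (length(cset)) max(pos_in_ord[cset]) else 0L, 0L)
  mass_at <- cumsum(vapply(0:m, function(t) sum(post[rank_in == t]), 0))
  t_hit <- which(mass_at >= rho - 1e-12)[1] - 1L  # mass_at[1] is prefix size 0
  if (is.na(t_hit)) t_hit <- m
  if (t_hit == 0L) t_hit <- 1L  # a credible set is never empty
  posterior$snp_ids[sort(ord[seq_len(t_hit)])]
}

#' @export
print.causal_posterior <- function(x, ...) {
  cat("Causal-configuration posterior over", length(x$pip), "SNPs (K <=",
      x$cfg$max_causal, ")\n  top SNP:", x$top_snp,
      sprintf("(PIP %.3f)", max(x$pip)),
      "\n  null-configuration posterior:", format(x$null_posterior),
      "\n  ", sprintf("%.0f%%", 100 * x$cfg$rho), "credible set:",
      paste(x$credible_set, collapse = ", "), "\n")
  invisible(x)
}
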