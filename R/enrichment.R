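# Quantile-quantile enrichment of candidate-region association p-values
# against a reference set, with order-statistic confidence envelopes.

#' Expected null quantiles and order-statistic envelope
#'
#' For n p-values sorted ascending, the i-th order statistic of the uniform
#' null is Beta(i, n - i + 1); the expected -log10 quantile uses the plotting
#' position `i/(n + 1)` and the envelope comes from the Beta quantiles at
#' `alpha/2` and `1 - alpha/2`, transformed to -log10. Rank 1 is the largest
#' -log10 p (smallest p).
#'
#' @param n number of p-values.
#' @param alpha envelope level complement (default 0.05 for a 95% envelope).
#' @return `data.frame` with `rank`, `expected`, `lower`, `upper` on the
#'   -log10 scale, rank 1 = most significant.
#' @export
qq_envelope <- function(n, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  i <- seq_len(n)
  data.frame(
    rank = i,
    expected = -log10(i / (n + 1)),
    lower = -log10(stats::qbeta(1 - alpha / 2, i, n - i + 1)),
    upper = -log10(stats::qbeta(alpha / 2, i, n - i + 1))
  )
}

#' Compare two association p-value sets on the quantile scale
#'
#' Sorts both sets on the -log10 scale (rank 1 = most significant), pairing
#' quantiles directly when the sets have equal size and by interpolation at
#' the plotting positions of set A otherwise. The tail-shift statistic is the
#' mean difference (A minus B) over the top decile of quantiles. Enrichment
#' of set A is flagged when any top-decile point of A exceeds the upper bound
#' of A's null envelope made simultaneous over the monitored tail points
#' (pointwise level `alpha / n_tail`, a union bound), so the null flag rate
#' is at most `alpha`.
#'
#' @param p_ours,p_reference p-value vectors (set A and set B).
#' @param alpha envelope level complement.
#' @return list of class `qq_comparison`: `quantiles` (data frame with
#'   paired -log10 quantiles and the envelope), `tail_shift`,
#'   `n_tail`, `enriched`, `n_exceed`.
#' @export
compare_sets <- function(p_ours, p_reference, alpha = 0.05) {
  if (!length(p_ours) || !length(p_reference))
    stop("empty p-value set")
  stopifnot(all(p_ours > 0), all(p_reference > 0))
  qa <- sort(-log10(p_ours), decreasing = TRUE)
  qb <- sort(-log10(p_reference), decreasing = TRUE)
  n <- length(qa)
  if (length(qb) != n) {
    probs <- seq_len(n) / (n + 1)
    qb <- -log10(stats::quantile(p_reference, probs, names = FALSE, type = 7))
    qb <- sort(qb, decreasing = TRUE)
  }
  env <- qq_envelope(n, alpha)
  n_tail <- max(1L, ceiling(n / 10))
  tail_idx <- seq_len(n_tail)
  tail_shift <- mean(qa[tail_idx] - qb[tail_idx])
  env_sim <- qq_envelope(n, alpha / n_tail)
  exceed <- qa[tail_idx] > env_sim$upper[tail_idx]
  out <- list(
    quantiles = data.frame(rank = env$rank, ours = qa, reference = qb,
                           expected = env$expected, lower = env$lower,
                           upper = env$upper),
    tail_shift = tail_shift, n_tail = n_tail,
    n_exceed = sum(exceed), enriched = any(exceed), alpha = alpha)
  class(out) <- "qq_comparison"
  out
}

#' @export
print.qq_comparison <- function(x, ...) {
  cat(sprintf(
    "QQ comparison over %d quantiles\n  tail shift (top %d quantiles): %.3f in -log10(p)\n  enrichment flag: %s (%d/%d tail points above the %.0f%% envelope)\n",
    nrow(x$quantiles), x$n_tail, x$tail_shift, x$enriched, x$n_exceed,
    x$n_tail, 100 * (1 - x$alpha)))
  invisible(x)
}
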