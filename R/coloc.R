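# Colocalization of two association signals from per-variant (log)
# Bayes factors: the five-hypothesis posterior decomposition, applied
# either to marginal summary statistics via Wakefield approximate Bayes
# factors or to per-effect Bayes factors from sum-of-single-effects fits
# (one credible-set pair at a time).

#' Wakefield approximate Bayes factor
#'
#' \deqn{\log ABF = 0.5 (\log(1 - r) + r z^2)} with `z = beta/se` and
#' `r = prior_sd^2 / (prior_sd^2 + se^2)`. Vectorized.
#'
#' @param beta Effect estimates.
#' @param se Standard errors (> 0).
#' @param prior_sd Prior SD of the true effect (default 0.15).
#' @return Log approximate Bayes factors.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) abort("standard errors must be positive")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

#' Colocalization posteriors from two log-Bayes-factor vectors
#'
#' Standard five-hypothesis decomposition over a shared variant universe:
#' H0 no association, H1/H2 association in one signal only, H3 two
#' distinct causal variants, H4 one shared causal variant. Sums are
#' log-sum-exp stabilized. Classification: `strong` if PP4 >= 0.8,
#' `moderate` if PP4 >= 0.5, else `none`.
#'
#' @param lbf_a,lbf_b Per-variant log Bayes factors, aligned.
#' @param p1,p2 Per-variant prior probabilities of causality in signal A
#'   / B only (defaults 1e-4).
#' @param p12 Per-variant prior of a shared causal variant (default
#'   5e-6).
#' @return One-row tibble: `pp0`..`pp4`, `classification`.
#' @export
coloc_posteriors <- function(lbf_a, lbf_b, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  stopifnot(length(lbf_a) == length(lbf_b))
  sa <- logsumexp(lbf_a)
  sb <- logsumexp(lbf_b)
  sab <- logsumexp(lbf_a + lbf_b)
  l0 <- 0
  l1 <- log(p1) + sa
  l2 <- log(p2) + sb
  # sum over ordered distinct pairs: (sum_i BF_Ai)(sum_j BF_Bj) - sum_i BF_Ai BF_Bi
  both <- sa + sb
  l3 <- if (both > sab) log(p1) + log(p2) + both + log1p(-exp(sab - both))
        else -Inf
  l4 <- log(p12) + sab
  lall <- c(l0, l1, l2, l3, l4)
  pp <- exp(lall - logsumexp(lall))
  pp <- pp / sum(pp)
  tibble::tibble(
    pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4], pp4 = pp[5],
    classification = if (pp[5] >= 0.8) "strong"
                     else if (pp[5] >= 0.5) "moderate" else "none"
  )
}

#' Credible-set-aware colocalization of two fine-mapping fits
#'
#' Applies [coloc_posteriors()] to every pair of surviving effects
#' (credible sets) between two [susie_fit()] objects, using each
#' effect's per-variant log Bayes factors. Fits must share the same
#' variant universe (matched by variant id; at least 10 shared).
#'
#' @param fit_a,fit_b `susie_fit` objects.
#' @param coverage,purity_min Passed to [extract_credible_sets()] to
#'   decide which effects survive.
#' @param ... Priors forwarded to [coloc_posteriors()].
#' @return Tibble with one row per effect pair: `effect_a`, `effect_b`,
#'   posteriors and classification.
#' @export
susie_coloc <- function(fit_a, fit_b, coverage = 0.95, purity_min = 0.5, ...) {
  shared <- intersect(fit_a$variant_id, fit_b$variant_id)
  if (length(shared) < 10) abort("fewer than 10 shared variants")
  ia <- match(shared, fit_a$variant_id)
  ib <- match(shared, fit_b$variant_id)
  sets_a <- extract_credible_sets(fit_a, coverage, purity_min)
  sets_b <- extract_credible_sets(fit_b, coverage, purity_min)
  if (nrow(sets_a) == 0 || nrow(sets_b) == 0) {
    return(tibble::tibble(effect_a = integer(), effect_b = integer(),
                          pp0 = double(), pp1 = double(), pp2 = double(),
                          pp3 = double(), pp4 = double(),
                          classification = character()))
  }
  out <- list()
  for (la in sets_a$effect) for (lb in sets_b$effect) {
    row <- coloc_posteriors(fit_a$lbf[la, ia], fit_b$lbf[lb, ib], ...)
    row$effect_a <- la
    row$effect_b <- lb
    out[[length(out) + 1]] <- row
  }
  dplyr::relocate(dplyr::bind_rows(out), "effect_a", "effect_b")
}
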