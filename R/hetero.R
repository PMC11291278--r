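# Effect-size heterogeneity (he-QTL) testing: one-tailed F-tests of
# genotype-by-continental-group interaction under single-causal and
# multi-causal (all-leads-conditioned) models, plus a genotype-by-PC
# variant.

#' Eligibility filter for interaction testing
#'
#' A variant is eligible when its MAF is at or above `maf_min` in at
#' least `min_groups` continental groups.
#'
#' @param af Long AF tibble from [group_af()] (`variant_id`, `group`,
#'   `maf`).
#' @param maf_min MAF threshold (default 0.05).
#' @param min_groups Minimum qualifying groups (default 2).
#' @return Tibble: `variant_id`, `n_groups_passing`, `eligible`.
#' @export
eligibility_filter <- function(af, maf_min = 0.05, min_groups = 2) {
  out <- dplyr::summarise(dplyr::group_by(af, .data$variant_id),
                          n_groups_passing = sum(.data$maf >= maf_min),
                          .groups = "drop")
  out$eligible <- out$n_groups_passing >= min_groups
  out
}

# F-test comparing full vs reduced OLS designs
nested_f_test <- function(y, X_reduced, X_full) {
  qr_r <- qr(X_reduced); qr_f <- qr(X_full)
  df1 <- qr_f$rank - qr_r$rank
  if (df1 < 1) abort("interaction terms are not estimable (no testable groups)")
  df2 <- length(y) - qr_f$rank
  if (df2 < 1) abort("no residual degrees of freedom")
  rss_r <- sum(qr.resid(qr_r, y)^2)
  rss_f <- sum(qr.resid(qr_f, y)^2)
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

interaction_design <- function(g_focal, groups, other_leads, covariates,
                               min_group_n = 5) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) {
    abort("focal variant polymorphic in fewer than two testable groups")
  }
  gm <- model.matrix(~groups)[, -1, drop = FALSE]
  base <- cbind(1, g_focal, other_leads, gm, covariates)
  # interaction columns only for groups where the focal variant is
  # polymorphic and with enough samples; first such group is the baseline
  lv <- levels(groups)
  poly <- vapply(lv, function(l) {
    idx <- groups == l
    sum(idx) >= min_group_n && length(unique(g_focal[idx])) > 1
  }, logical(1))
  testable <- lv[poly]
  if (length(testable) < 2) {
    abort("focal variant polymorphic in fewer than two testable groups")
  }
  inter <- vapply(testable[-1], function(l) g_focal * (groups == l),
                  numeric(length(g_focal)))
  inter <- matrix(inter, ncol = length(testable) - 1,
                  dimnames = list(NULL, paste0("gx", testable[-1])))
  list(reduced = base, full = cbind(base, inter),
       groups_tested = testable)
}

#' Genotype-by-group interaction test, single-causal model
#'
#' Full model `y ~ g + group + g:group + covariates` against the reduced
#' model without the interaction; one-tailed (upper tail) F-test.
#' Interaction terms are built only for groups where the focal variant is
#' polymorphic and that contribute at least `min_group_n` samples.
#'
#' @param y Prepared phenotype vector.
#' @param g_focal Focal-variant dosage vector.
#' @param samples Sample table.
#' @param covariates Optional samples x covariates matrix.
#' @param min_group_n Minimum samples for a group to enter the
#'   interaction (default 5).
#' @return One-row tibble: `model`, `f`, `df1`, `df2`, `p`,
#'   `n_leads_in_model`, `groups_tested`.
#' @export
interaction_test_single <- function(y, g_focal, samples, covariates = NULL,
                                    min_group_n = 5) {
  interaction_test_multi(y, matrix(g_focal, ncol = 1), 1L, samples,
                         covariates, min_group_n, model_label = "single")
}

#' Genotype-by-group interaction test, multi-causal model
#'
#' Includes every lead dosage as an additive predictor and tests the
#' interaction of the focal lead only:
#' `y ~ sum_k g_k + group + g_focal:group + covariates` against the model
#' without `g_focal:group`. Collinear leads are dropped (later one).
#'
#' @param y Prepared phenotype vector.
#' @param lead_dosages Matrix n x K of lead dosages.
#' @param focal Column index (or name) of the focal lead.
#' @param samples Sample table.
#' @param covariates Optional samples x covariates matrix.
#' @param min_group_n Minimum group size for interaction terms.
#' @param model_label Label stored in the result (`"multi"` by default).
#' @return One-row tibble as in [interaction_test_single()].
#' @export
interaction_test_multi <- function(y, lead_dosages, focal, samples,
                                   covariates = NULL, min_group_n = 5,
                                   model_label = "multi") {
  G <- as.matrix(lead_dosages)
  if (is.character(focal)) focal <- match(focal, colnames(G))
  stopifnot(!is.na(focal), focal >= 1, focal <= ncol(G))
  samples <- as_sample_table(samples)
  drop <- rep(FALSE, ncol(G))
  if (ncol(G) > 1) {
    cm <- abs(cor(G))
    for (j in seq_len(ncol(G))[-1]) {
      prev <- seq_len(j - 1)
      if (any(cm[j, prev][!drop[prev]] > 1 - 1e-10)) drop[j] <- TRUE
    }
    if (drop[focal]) abort("focal lead is collinear with an earlier lead")
    if (any(drop)) warn(sprintf("dropping %d collinear lead(s)", sum(drop)))
  }
  Gk <- G[, !drop, drop = FALSE]
  focal_k <- sum(!drop[seq_len(focal)])
  others <- Gk[, -focal_k, drop = FALSE]
  des <- interaction_design(Gk[, focal_k], samples$continental_group,
                            if (ncol(others)) others else NULL,
                            covariates, min_group_n)
  ft <- nested_f_test(y, des$reduced, des$full)
  tibble::tibble(
    model = model_label, f = ft$f, df1 = ft$df1, df2 = ft$df2, p = ft$p,
    n_leads_in_model = ncol(Gk),
    groups_tested = paste(des$groups_tested, collapse = ",")
  )
}

#' Genotype-by-genotype-PC interaction test
#'
#' Replaces the categorical group interaction with `g x PC_j` terms for
#' the supplied genotype principal components.
#'
#' @param y Prepared phenotype vector.
#' @param g_focal Focal dosage vector.
#' @param pcs Samples x PCs matrix (>= 1 column).
#' @param covariates Optional samples x covariates matrix.
#' @return One-row tibble as in [interaction_test_single()] with
#'   `model = "pcs"`.
#' @export
interaction_test_pcs <- function(y, g_focal, pcs, covariates = NULL) {
  pcs <- as.matrix(pcs)
  stopifnot(ncol(pcs) >= 1)
  base <- cbind(1, g_focal, pcs, covariates)
  inter <- pcs * g_focal
  colnames(inter) <- paste0("gxPC", seq_len(ncol(pcs)))
  ft <- nested_f_test(y, base, cbind(base, inter))
  tibble::tibble(model = "pcs", f = ft$f, df1 = ft$df1, df2 = ft$df2,
                 p = ft$p, n_leads_in_model = 1L,
                 groups_tested = paste0("PC1-", ncol(pcs)))
}

#' Genotype principal components
#'
#' PCs of the centered dosage matrix (samples as observations), the
#' continuous ancestry axes used by [interaction_test_pcs()].
#'
#' @param genotypes A [genotype_matrix()] or dosage matrix.
#' @param n_pcs Number of components (default 2).
#' @return Samples x `n_pcs` matrix.
#' @export
genotype_pcs <- function(genotypes, n_pcs = 2) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  keep <- apply(dos, 1, function(x) length(unique(x)) > 1)
  pc <- prcomp(t(dos[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  m <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  colnames(m) <- paste0("PC", seq_len(ncol(m)))
  m
}

#' Bonferroni summary of interaction tests
#'
#' Applies the Bonferroni threshold `alpha / n_tests` within each model
#' family and tabulates significant counts, optionally stratified by the
#' gene's number of credible sets.
#'
#' @param results Tibble of interaction results with columns `model`,
#'   `p`, and optionally `gene_id` and `n_credible_sets`.
#' @param alpha Family-wise error target (default 0.05).
#' @return List: `results` (input plus `bonferroni_significant`),
#'   `counts` per model, `strata` per (model, n_credible_sets) when
#'   available.
#' @export
bonferroni_summary <- function(results, alpha = 0.05) {
  out <- dplyr::mutate(dplyr::group_by(results, .data$model),
                       n_tests = dplyr::n(),
                       bonferroni_significant = .data$p <= alpha / dplyr::n())
  out <- dplyr::ungroup(out)
  counts <- dplyr::summarise(dplyr::group_by(out, .data$model),
                             n_tests = dplyr::n(),
                             n_significant = sum(.data$bonferroni_significant),
                             .groups = "drop")
  strata <- NULL
  if ("n_credible_sets" %in% names(out)) {
    strata <- dplyr::summarise(
      dplyr::group_by(out, .data$model, .data$n_credible_sets),
      n_tests = dplyr::n(),
      n_significant = sum(.data$bonferroni_significant),
      frac_significant = mean(.data$bonferroni_significant),
      .groups = "drop")
  }
  list(results = out, counts = counts, strata = strata)
}
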