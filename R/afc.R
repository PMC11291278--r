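# Allelic fold change (aFC) effect sizes: log2 ratio of expression of the
# alternative-allele haplotype to the reference haplotype, estimated from
# dosage genotypes under a multiplicative model, marginally or jointly
# (conditional on all other lead QTLs of the gene).

# log2 of the dosage-expected relative expression ((2-g) + g*k)/2 with
# k = 2^log2k
afc_term <- function(g, log2k) log2((2 - g) + g * 2^log2k) - 1

afc_sse <- function(l2y, G, log2k) {
  pred <- rep(0, length(l2y))
  for (j in seq_len(ncol(G))) pred <- pred + afc_term(G[, j], log2k[j])
  resid <- l2y - pred
  sum((resid - mean(resid))^2)     # profiles out the intercept log2(C)
}

#' Marginal aFC estimate for one variant
#'
#' Fits \eqn{E[y | g] = C((2-g) + gk)/2} by least squares on the log2
#' scale; `log2_afc = log2(k)`, constrained to |log2 k| <= `cap`
#' (default 100-fold).
#'
#' @param y Expression on the linear scale, strictly positive (counts
#'   scaled by size factors plus a pseudocount of 1).
#' @param g Dosage vector in 0/1/2.
#' @param cap Bound on |log2 aFC| (default `log2(100)`).
#' @param n_boot Bootstrap resamples for the standard error (default 0:
#'   no SE).
#' @return Tibble: `log2_afc`, `se`, `capped`, `n_leads_conditioned` (= 1).
#' @export
afc_single <- function(y, g, cap = log2(100), n_boot = 0) {
  afc_conditional(y, matrix(g, ncol = 1), cap = cap, n_boot = n_boot)
}

#' Conditional aFC estimates for a gene's lead QTLs
#'
#' Joint multiplicative model
#' \eqn{E[y|g_1..g_K] = C \prod_k ((2-g_k) + g_k k_k)/2}, fitted by
#' box-constrained least squares on the log2 scale with the intercept
#' profiled out, initialized from the marginal fits. Perfectly collinear
#' leads are dropped (later one wins the flag).
#'
#' @param y Linear-scale expression, strictly positive.
#' @param G_leads Matrix n x K of lead dosages (columns named by variant).
#' @param cap Bound on each |log2 k|.
#' @param n_boot Bootstrap resamples for standard errors (default 200;
#'   0 skips).
#' @param seed Seed for the bootstrap.
#' @param haplotypes Optional list of two n x K 0/1 allele matrices
#'   (`hap1`, `hap2`, summing to `G_leads`). When supplied, the exact
#'   phased model is fitted: each haplotype contributes
#'   \eqn{\prod_k 2^{\beta_k a_k}} and the individual mean is the
#'   haplotype average. The dosage model is exact for a single lead and
#'   an approximation for several.
#' @return Tibble with one row per retained lead: `lead_variant_id`,
#'   `log2_afc`, `se`, `capped`, `n_leads_conditioned`, `dropped_collinear`.
#' @export
afc_conditional <- function(y, G_leads, cap = log2(100), n_boot = 200,
                            seed = 1, haplotypes = NULL) {
  G <- as.matrix(G_leads)
  stopifnot(length(y) == nrow(G), all(y > 0))
  vid <- colnames(G) %||% sprintf("lead%d", seq_len(ncol(G)))
  mono <- apply(G, 2, function(x) length(unique(x)) < 2)
  if (any(mono)) abort("monomorphic lead dosage")
  drop <- rep(FALSE, ncol(G))
  if (ncol(G) > 1) {
    cm <- abs(cor(G))
    for (j in 2:ncol(G)) {
      if (any(cm[j, seq_len(j - 1)][!drop[seq_len(j - 1)]] > 1 - 1e-10)) drop[j] <- TRUE
    }
  }
  if (any(drop)) warn(sprintf("dropping %d collinear lead(s)", sum(drop)))
  keep <- which(!drop)
  Gk <- G[, keep, drop = FALSE]
  K <- ncol(Gk)
  l2y <- log2(y)
  H <- NULL
  if (!is.null(haplotypes)) {
    H <- list(as.matrix(haplotypes[[1]])[, keep, drop = FALSE],
              as.matrix(haplotypes[[2]])[, keep, drop = FALSE])
    stopifnot(all(H[[1]] + H[[2]] == Gk))
  }
  sse_fun <- function(l2y_b, G_b, H_b) {
    if (is.null(H_b)) {
      function(b) afc_sse(l2y_b, G_b, b)
    } else {
      function(b) {
        pred <- log2(2^(H_b[[1]] %*% b) + 2^(H_b[[2]] %*% b)) - 1
        resid <- l2y_b - pred
        sum((resid - mean(resid))^2)
      }
    }
  }
  fit_one <- function(l2y_b, G_b, H_b = NULL) {
    init <- vapply(seq_len(K), function(j) {
      o <- optimize(function(b) afc_sse(l2y_b, G_b[, j, drop = FALSE], b),
                    interval = c(-cap, cap), tol = 1e-9)
      o$minimum
    }, numeric(1))
    f <- sse_fun(l2y_b, G_b, H_b)
    if (K == 1 && is.null(H_b)) return(init)
    opt <- optim(init, f, method = "L-BFGS-B",
                 lower = rep(-cap, K), upper = rep(cap, K),
                 control = list(factr = 1e4))
    opt$par
  }
  est <- fit_one(l2y, Gk, H)
  se <- rep(NA_real_, K)
  if (n_boot > 0) {
    set.seed(seed)
    bb <- matrix(NA_real_, n_boot, K)
    n <- length(y)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      Gb <- Gk[idx, , drop = FALSE]
      if (any(apply(Gb, 2, function(x) length(unique(x)) < 2))) next
      Hb <- if (is.null(H)) NULL else list(H[[1]][idx, , drop = FALSE],
                                           H[[2]][idx, , drop = FALSE])
      bb[b, ] <- fit_one(l2y[idx], Gb, Hb)
    }
    se <- apply(bb, 2, sd, na.rm = TRUE)
  }
  out <- tibble::tibble(
    lead_variant_id = vid[keep],
    log2_afc = est,
    se = se,
    capped = abs(est) >= cap - 1e-4,
    n_leads_conditioned = K,
    dropped_collinear = FALSE
  )
  if (any(drop)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      lead_variant_id = vid[drop], log2_afc = NA_real_, se = NA_real_,
      capped = FALSE, n_leads_conditioned = K, dropped_collinear = TRUE))
  }
  out
}

#' Linear-scale expression for aFC estimation
#'
#' Counts scaled by the median-of-ratios size factors with a pseudocount
#' of 1, kept on the linear scale.
#'
#' @param pheno Counts [phenotype_matrix()].
#' @return Matrix of positive linear-scale values (features x samples).
#' @export
afc_expression <- function(pheno) {
  norm <- normalize_expression(pheno)
  2^norm$values          # log2(count/sf + 1) back to linear: count/sf + 1
}
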