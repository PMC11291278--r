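# Sum-of-single-effects fine-mapping fitted by iterative Bayesian
# stepwise selection (IBSS), 95% credible-set extraction with purity
# filtering, intron-to-gene credible-set merging, and lead selection.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bayesian single-effect regression
#'
#' Computes, for each column of `X`, the Bayes factor of the univariate
#' Gaussian-prior regression of `y` on that column, the posterior
#' inclusion weights (uniform prior over columns), and the per-variant
#' posterior moments of the effect.
#'
#' @param y Centered response vector.
#' @param X Centered predictor matrix (n x p).
#' @param prior_var Prior variance of the single effect.
#' @param residual_var Residual variance.
#' @return List: `alpha` (posterior inclusion weights, sums to 1), `lbf`
#'   (per-variant log Bayes factors), `lbf_model` (log BF of the
#'   single-effect model vs null), `mu` and `mu2` (posterior mean and
#'   second moment of the effect given inclusion), `betahat`, `shat2`.
#' @export
single_effect_regression <- function(y, X, prior_var, residual_var) {
  if (residual_var <= 0) abort("residual variance must be positive")
  d <- pmax(colSums(X^2), .Machine$double.eps)
  Xty <- as.vector(crossprod(X, y))
  betahat <- Xty / d
  shat2 <- residual_var / d
  if (prior_var <= 0) {
    p <- ncol(X)
    return(list(alpha = rep(1 / p, p), lbf = rep(0, p), lbf_model = 0,
                mu = rep(0, p), mu2 = rep(0, p),
                betahat = betahat, shat2 = shat2))
  }
  lbf <- 0.5 * log(shat2 / (prior_var + shat2)) +
    0.5 * betahat^2 / shat2 * prior_var / (prior_var + shat2)
  w <- exp(lbf - max(lbf))
  alpha <- w / sum(w)
  post_var <- 1 / (1 / prior_var + d / residual_var)
  mu <- post_var * Xty / residual_var
  mu2 <- post_var + mu^2
  list(alpha = alpha, lbf = lbf,
       lbf_model = logsumexp(lbf) - log(ncol(X)),
       mu = mu, mu2 = mu2, betahat = betahat, shat2 = shat2)
}

# maximize the single-effect log Bayes factor over the prior variance;
# the previous value is a fallback candidate so the coordinate update can
# never decrease the objective (keeps the ELBO monotone)
optimize_prior_var <- function(betahat, shat2, v_prev = 0) {
  f <- function(lv) {
    v <- exp(lv)
    lbf <- 0.5 * log(shat2 / (v + shat2)) +
      0.5 * betahat^2 / shat2 * v / (v + shat2)
    logsumexp(lbf) - log(length(lbf))
  }
  opt <- optimize(f, interval = c(-30, 10), maximum = TRUE)
  best_v <- exp(opt$maximum)
  best_obj <- opt$objective
  if (v_prev > 0 && f(log(v_prev)) > best_obj) {
    best_v <- v_prev
    best_obj <- f(log(v_prev))
  }
  if (best_obj <= 1e-10) 0 else best_v
}

#' Fit the sum-of-single-effects model by IBSS
#'
#' Cycles over `L` additive single effects; each is refitted by
#' [single_effect_regression()] against the residual of all other
#' effects, with its prior variance re-estimated by maximizing its
#' single-effect likelihood. The residual variance is updated from the
#' expected residual sum of squares. Iteration stops when the evidence
#' lower bound (ELBO) changes by less than `tol`.
#'
#' @param y Response vector (centered internally).
#' @param X Predictor matrix, n x p (dosages in columns; centered
#'   internally).
#' @param L Maximum number of effects (default 10).
#' @param max_iter Maximum IBSS sweeps (default 100).
#' @param tol ELBO convergence tolerance (default 1e-4).
#' @return An object of class `susie_fit`: `alpha` (L x p), `mu`, `mu2`,
#'   `lbf` (L x p), `lbf_model` (per effect), `prior_var` (per effect),
#'   `pip` (marginal, over active effects), `sigma2`, `elbo` (trace),
#'   `converged`, `n_iter`, `variant_id`.
#' @export
susie_fit <- function(y, X, L = 10, max_iter = 100, tol = 1e-4) {
  X <- as.matrix(X)
  y <- as.vector(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > 10, p >= 1)
  L <- min(L, p)
  vid <- colnames(X) %||% sprintf("x%d", seq_len(p))
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  d <- pmax(colSums(Xc^2), .Machine$double.eps)
  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  mu2 <- matrix(0, L, p)
  lbf <- matrix(0, L, p)
  lbf_model <- numeric(L)
  V <- rep(var(yc) * 0.2, L)
  sigma2 <- var(yc)
  B <- alpha * mu                       # L x p posterior mean effects
  Xb_l <- Xc %*% t(B)                   # n x L fitted values per effect
  R <- yc - rowSums(Xb_l)
  elbo <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    kl <- numeric(L)
    for (l in seq_len(L)) {
      r_l <- R + Xb_l[, l]
      Xtr <- as.vector(crossprod(Xc, r_l))
      betahat <- Xtr / d
      shat2 <- sigma2 / d
      V[l] <- optimize_prior_var(betahat, shat2, v_prev = V[l])
      ser <- single_effect_regression(r_l, Xc, V[l], sigma2)
      alpha[l, ] <- ser$alpha
      mu[l, ] <- ser$mu
      mu2[l, ] <- ser$mu2
      lbf[l, ] <- ser$lbf
      lbf_model[l] <- ser$lbf_model
      b_l <- ser$alpha * ser$mu
      Xb_l[, l] <- Xc %*% b_l
      R <- r_l - Xb_l[, l]
      kl[l] <- -ser$lbf_model +
        (1 / (2 * sigma2)) * (2 * sum(b_l * Xtr) - sum(d * ser$alpha * ser$mu2))
    }
    erss <- sum(R^2) - sum(Xb_l^2) +
      sum(sweep(alpha * mu2, 2, d, "*"))
    elbo <- c(elbo, -n / 2 * log(2 * pi * sigma2) - erss / (2 * sigma2) - sum(kl))
    if (it > 1 && abs(elbo[it] - elbo[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    sigma2 <- max(erss / n, .Machine$double.eps)
  }
  active <- V > 1e-9
  pip <- if (any(active)) {
    1 - apply(1 - alpha[active, , drop = FALSE], 2, prod)
  } else rep(0, p)
  structure(
    list(alpha = alpha, mu = mu, mu2 = mu2, lbf = lbf,
         lbf_model = lbf_model, prior_var = V, pip = setNames(pip, vid),
         sigma2 = sigma2, elbo = elbo, converged = converged,
         n_iter = length(elbo), variant_id = vid, X = Xc),
    class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("<susie_fit> L = %d, %d variants, %d iterations (%s), %d active effect(s)\n",
              nrow(x$alpha), ncol(x$alpha), x$n_iter,
              if (x$converged) "converged" else "not converged",
              sum(x$prior_var > 1e-9)))
  invisible(x)
}

#' @rdname susie_fit
#' @param x A `susie_fit`.
#' @param ... Unused.
#' @method tidy susie_fit
#' @export
tidy.susie_fit <- function(x, ...) {
  tibble::tibble(variant_id = x$variant_id, pip = unname(x$pip))
}

#' @rdname susie_fit
#' @method glance susie_fit
#' @export
glance.susie_fit <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, converged = x$converged,
                 elbo = tail(x$elbo, 1), sigma2 = x$sigma2,
                 n_active = sum(x$prior_var > 1e-9))
}

set_purity <- function(X, members) {
  if (length(members) < 2) return(1)
  if (length(members) > 100) members <- sample(members, 100)
  cm <- abs(cor(X[, members, drop = FALSE]))
  min(cm[upper.tri(cm)])
}

#' Extract credible sets from a fit
#'
#' Per active effect: variants sorted by posterior inclusion weight, the
#' smallest prefix with cumulative weight at or above `coverage` forms the
#' set. Sets whose purity (minimum absolute pairwise genotype
#' correlation) is at or below `purity_min` are dropped, as are effects
#' with a vanishing estimated prior variance; identical sets are
#' deduplicated.
#'
#' @param fit A [susie_fit()].
#' @param coverage Target cumulative inclusion weight (default 0.95).
#' @param purity_min Purity threshold (default 0.5).
#' @return Tibble with one row per retained set: `set_id`, `effect`,
#'   `coverage_attained`, `purity`, `n_variants`, and a `variants`
#'   list-column of tibbles (`variant_id`, `alpha`, `pip`).
#' @export
extract_credible_sets <- function(fit, coverage = 0.95, purity_min = 0.5) {
  out <- list()
  seen <- character(0)
  for (l in seq_len(nrow(fit$alpha))) {
    if (fit$prior_var[l] <= 1e-9) next
    o <- order(fit$alpha[l, ], decreasing = TRUE)
    csum <- cumsum(fit$alpha[l, o])
    k <- which(csum >= coverage)[1]
    if (is.na(k)) k <- length(o)
    members <- o[seq_len(k)]
    key <- paste(sort(members), collapse = ",")
    if (key %in% seen) next
    pur <- set_purity(fit$X, members)
    if (pur <= purity_min) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- tibble::tibble(
      set_id = sprintf("L%d", l), effect = l,
      coverage_attained = csum[k], purity = pur, n_variants = k,
      variants = list(tibble::tibble(
        variant_id = fit$variant_id[members],
        alpha = fit$alpha[l, members],
        pip = unname(fit$pip[members])))
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(set_id = character(), effect = integer(),
                          coverage_attained = double(), purity = double(),
                          n_variants = integer(), variants = list()))
  }
  dplyr::bind_rows(out)
}

#' Select the lead variant of a credible set
#'
#' Highest PIP wins; ties break to the smaller |TSS distance|, then to the
#' lexicographically smaller variant id.
#'
#' @param variants Tibble with `variant_id`, `pip`, and optionally
#'   `tss_distance`.
#' @return The lead `variant_id`.
#' @export
select_lead <- function(variants) {
  stopifnot(nrow(variants) > 0)
  dist <- if ("tss_distance" %in% names(variants)) abs(variants$tss_distance)
          else rep(0, nrow(variants))
  ord <- order(-variants$pip, dist, variants$variant_id)
  variants$variant_id[ord[1]]
}

#' Merge intron-level credible sets into gene-level sets
#'
#' Builds a graph over a gene's intron-level sets with an edge whenever
#' two sets share at least one variant, and merges connected components
#' to closure. A merged set is the union of member variants with PIP
#' taken as the maximum across contributing sets; the lead is
#' re-selected.
#'
#' @param sets Flat tibble with columns `gene_id`, `set_id`,
#'   `variant_id`, `pip`, and optionally `tss_distance`.
#' @return Tibble with one row per gene-level set: `gene_id`, `set_id`,
#'   `n_source_sets`, `n_variants`, `lead_variant_id`, and a `variants`
#'   list-column.
#' @export
merge_intron_sets_to_gene <- function(sets) {
  stopifnot(all(c("gene_id", "set_id", "variant_id", "pip") %in% names(sets)))
  out <- list()
  for (g in unique(sets$gene_id)) {
    sg <- sets[sets$gene_id == g, ]
    ids <- unique(sg$set_id)
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    vlists <- lapply(ids, function(s) unique(sg$variant_id[sg$set_id == s]))
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      if (length(intersect(vlists[[i]], vlists[[j]])) > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    comp <- vapply(seq_along(ids), find, integer(1))
    for (ci in unique(comp)) {
      member_sets <- ids[comp == ci]
      sv <- sg[sg$set_id %in% member_sets, ]
      merged <- dplyr::summarise(
        dplyr::group_by(sv, .data$variant_id),
        pip = max(.data$pip),
        tss_distance = if ("tss_distance" %in% names(sv)) .data$tss_distance[1] else NA_real_,
        .groups = "drop")
      out[[length(out) + 1]] <- tibble::tibble(
        gene_id = g,
        set_id = sprintf("%s_cs%d", g, length(out) + 1),
        n_source_sets = length(member_sets),
        n_variants = nrow(merged),
        lead_variant_id = select_lead(merged),
        variants = list(merged)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), set_id = character(),
                          n_source_sets = integer(), n_variants = integer(),
                          lead_variant_id = character(), variants = list()))
  }
  dplyr::bind_rows(out)
}

#' Fine-map one feature
#'
#' Convenience wrapper: cis candidates, [susie_fit()] on their dosages,
#' and [extract_credible_sets()] with TSS distances and lead variants
#' attached.
#'
#' @param y Prepared phenotype vector.
#' @param genotypes A [genotype_matrix()].
#' @param chrom,tss Feature location.
#' @param maf_min Candidate MAF floor.
#' @param L,coverage,purity_min,max_iter,tol Model settings (see
#'   [susie_fit()] and [extract_credible_sets()]).
#' @return List: `fit` (the `susie_fit`), `sets` (tibble with
#'   `lead_variant_id` added).
#' @export
finemap_feature <- function(y, genotypes, chrom, tss, maf_min = 0.01,
                            L = 10, coverage = 0.95, purity_min = 0.5,
                            max_iter = 100, tol = 1e-4) {
  cand <- cis_candidates(genotypes, chrom, tss, maf_min)
  if (length(cand) == 0) abort("no cis candidates to fine-map")
  X <- t(genotypes$dosages[cand, , drop = FALSE])
  fit <- susie_fit(y, X, L = L, max_iter = max_iter, tol = tol)
  sets <- extract_credible_sets(fit, coverage, purity_min)
  if (nrow(sets) > 0) {
    pos <- genotypes$variants$pos[match(fit$variant_id, genotypes$variants$variant_id)]
    sets$variants <- lapply(sets$variants, function(v) {
      v$tss_distance <- pos[match(v$variant_id, fit$variant_id)] - tss
      v
    })
    sets$lead_variant_id <- vapply(sets$variants, select_lead, character(1))
  } else {
    sets$lead_variant_id <- character(0)
  }
  list(fit = fit, sets = sets)
}
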