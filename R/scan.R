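# Nominal cis association scanning and permutation-based gene-level
# eGene/sGene calling (adaptive permutations + Beta approximation).

#' Select cis candidate variants for a feature
#'
#' Variants on the feature's chromosome with position within 1 Mb of the
#' TSS (inclusive on both ends) and sample MAF at or above `maf_min`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param chrom,tss Feature location (TSS 1-based).
#' @param maf_min MAF floor (default 0.01).
#' @param window Window half-width in bp (default 1e6).
#' @return Integer vector of variant row indices (possibly empty).
#' @export
cis_candidates <- function(genotypes, chrom, tss, maf_min = 0.01, window = 1e6) {
  v <- genotypes$variants
  idx <- which(v$chrom == chrom & v$pos >= tss - window & v$pos <= tss + window)
  if (length(idx) == 0) return(integer(0))
  af <- rowMeans(genotypes$dosages[idx, , drop = FALSE]) / 2
  maf <- pmin(af, 1 - af)
  idx[maf >= maf_min]
}

#' Nominal cis scan for one feature
#'
#' Simple linear regression of the prepared phenotype on each candidate
#' dosage. With `r` the sample correlation, `t = r * sqrt(df / (1 - r^2))`
#' with `df = n - 2 - k` where `k` covariates were residualized out of the
#' phenotype upstream.
#'
#' @param y Prepared phenotype vector (inverse-normal transformed and
#'   residualized).
#' @param genotypes A [genotype_matrix()].
#' @param candidates Integer variant rows from [cis_candidates()].
#' @param tss Feature TSS for the signed distance column.
#' @param df_adjust Number of covariates residualized out of `y`.
#' @return Tibble: `variant_id`, `slope`, `slope_se`, `t`, `p`, `maf`,
#'   `tss_distance`.
#' @export
nominal_scan <- function(y, genotypes, candidates, tss, df_adjust = 0) {
  if (length(candidates) == 0) abort("no candidate variants")
  G <- genotypes$dosages[candidates, , drop = FALSE]
  af <- rowMeans(G) / 2
  if (any(af == 0 | af == 1)) abort("monomorphic candidate passed to nominal_scan")
  n <- length(y)
  df <- n - 2 - df_adjust
  yc <- y - mean(y)
  gc <- G - rowMeans(G)
  sy <- sqrt(sum(yc^2))
  sg <- sqrt(rowSums(gc^2))
  r <- as.vector(gc %*% yc) / (sg * sy)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  slope <- r * sy / sg
  se <- ifelse(abs(tstat) > 0, abs(slope / tstat), sy / sg / sqrt(df))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tibble::tibble(
    variant_id = genotypes$variants$variant_id[candidates],
    slope = unname(slope), slope_se = unname(se), t = unname(tstat),
    p = unname(p),
    maf = unname(pmin(af, 1 - af)),
    tss_distance = genotypes$variants$pos[candidates] - tss
  )
}

fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- var(x)
  a0 <- max(m * (m * (1 - m) / max(v, 1e-12) - 1), 1e-3)
  b0 <- max((1 - m) * a0 / m, 1e-3)
  nll <- function(par) -sum(dbeta(x, exp(par[1]), exp(par[2]), log = TRUE))
  fit <- tryCatch(optim(log(c(a0, b0)), nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    return(list(shape1 = NA_real_, shape2 = NA_real_, converged = FALSE))
  }
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]),
       converged = fit$convergence == 0)
}

#' Permutation pass for one feature
#'
#' Permutes the phenotype across samples, records the best nominal p per
#' permutation, fits a Beta(a, b) distribution to the permuted minima by
#' maximum likelihood, and evaluates the observed best p under its CDF
#' (the FastQTL-style approximation). The direct empirical p
#' `(1 + #better) / (1 + n_perm)` is always reported; it is also the
#' fallback when the Beta fit fails. With `adaptive = TRUE`, permutations
#' run in blocks of 100 and stop once `adapt_min` permutations beat the
#' observed best p.
#'
#' @inheritParams nominal_scan
#' @param n_perm Maximum number of permutations (>= 100).
#' @param seed Integer seed.
#' @param adaptive Stop early for clearly null features.
#' @param adapt_min Exceedance count triggering early stop.
#' @return A list: `p_nominal_best`, `best_variant_id`, `p_beta`,
#'   `p_direct`, `beta_shape1`, `beta_shape2`, `n_perm_used`,
#'   `beta_converged`.
#' @export
permutation_pass <- function(y, genotypes, candidates, tss, n_perm = 1000,
                             seed = 1, df_adjust = 0, adaptive = FALSE,
                             adapt_min = 100) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  G <- genotypes$dosages[candidates, , drop = FALSE]
  n <- length(y)
  df <- n - 2 - df_adjust
  gc <- G - rowMeans(G)
  gs <- gc / sqrt(rowSums(gc^2))
  yc <- y - mean(y)
  ys <- yc / sqrt(sum(yc^2))
  r_obs <- abs(as.vector(gs %*% ys))
  best_i <- which.max(r_obs)
  r2p <- function(r) {
    t2 <- r^2 * df / pmax(1 - r^2, .Machine$double.eps)
    2 * pt(sqrt(t2), df, lower.tail = FALSE)
  }
  p_obs <- r2p(r_obs[best_i])
  best_p_perm <- numeric(0)
  done <- 0L
  while (done < n_perm) {
    blk <- min(100L, n_perm - done)
    P <- matrix(ys[sapply(seq_len(blk), function(i) sample.int(n))], nrow = n)
    rmax <- apply(abs(crossprod(t(gs), P)), 2, max)
    best_p_perm <- c(best_p_perm, r2p(rmax))
    done <- done + blk
    if (adaptive && sum(best_p_perm <= p_obs) >= adapt_min && done >= 100L) break
  }
  p_direct <- (1 + sum(best_p_perm <= p_obs)) / (1 + done)
  bf <- fit_beta_ml(best_p_perm)
  p_beta <- if (bf$converged) pbeta(p_obs, bf$shape1, bf$shape2) else p_direct
  if (!bf$converged) warn("Beta fit did not converge; using direct empirical p")
  list(p_nominal_best = p_obs,
       best_variant_id = genotypes$variants$variant_id[candidates[best_i]],
       p_beta = p_beta, p_direct = p_direct,
       beta_shape1 = bf$shape1, beta_shape2 = bf$shape2,
       n_perm_used = done, beta_converged = bf$converged)
}

#' Call eGenes/sGenes at a target FDR
#'
#' Benjamini-Hochberg q-values over the gene-level empirical p-values; a
#' gene is an eGene iff `q <= fdr`. When Beta parameters are available,
#' the per-gene nominal significance threshold is the Beta quantile at
#' the empirical-p cutoff halfway between the last accepted and first
#' rejected gene (used to count significant variant-gene pairs).
#'
#' @param genes Tibble with columns `gene_id`, `p_beta`, and optionally
#'   `beta_shape1`, `beta_shape2`.
#' @param fdr Target FDR (default 0.05).
#' @return The input tibble plus `q_value`, `is_egene`, and
#'   `nominal_threshold` columns.
#' @export
call_egenes <- function(genes, fdr = 0.05) {
  if (nrow(genes) == 0) abort("empty gene table")
  stopifnot(all(c("gene_id", "p_beta") %in% names(genes)))
  genes$q_value <- p.adjust(genes$p_beta, method = "BH")
  genes$is_egene <- genes$q_value <= fdr
  thr_emp <- if (any(genes$is_egene)) {
    acc <- max(genes$p_beta[genes$is_egene])
    rej <- suppressWarnings(min(genes$p_beta[!genes$is_egene]))
    if (is.finite(rej)) (acc + rej) / 2 else acc
  } else 0
  if (all(c("beta_shape1", "beta_shape2") %in% names(genes))) {
    genes$nominal_threshold <- ifelse(
      is.na(genes$beta_shape1), NA_real_,
      qbeta(thr_emp, genes$beta_shape1, genes$beta_shape2))
  } else {
    genes$nominal_threshold <- NA_real_
  }
  attr(genes, "empirical_p_threshold") <- thr_emp
  genes
}

#' Scan all features of a study
#'
#' Runs [cis_candidates()], [nominal_scan()] and [permutation_pass()] per
#' feature, then [call_egenes()].
#'
#' @param pheno Prepared [phenotype_matrix()] (see [prepare_phenotypes()]).
#' @param genotypes A [genotype_matrix()].
#' @param maf_min MAF floor for candidates.
#' @param n_perm,adaptive,adapt_min Permutation-pass settings.
#' @param fdr Gene-level FDR.
#' @param seed Integer seed (per-feature seeds derive from it).
#' @param df_adjust Covariates residualized out of the phenotype.
#' @return List: `genes` (gene-level tibble with eGene calls), `nominal`
#'   (per-pair tibble for scanned features), `skipped` (features without
#'   candidates).
#' @export
scan_study <- function(pheno, genotypes, maf_min = 0.01, n_perm = 1000,
                       adaptive = TRUE, adapt_min = 100, fdr = 0.05,
                       seed = 1, df_adjust = attr(pheno, "n_covariates") %||% 0) {
  feats <- pheno$features
  rows <- list(); noms <- list(); skipped <- character(0)
  for (i in seq_len(nrow(feats))) {
    cand <- cis_candidates(genotypes, feats$chrom[i], feats$tss[i], maf_min)
    if (length(cand) == 0) {
      skipped <- c(skipped, feats$feature_id[i])
      next
    }
    y <- pheno$values[i, ]
    nom <- nominal_scan(y, genotypes, cand, feats$tss[i], df_adjust)
    nom$feature_id <- feats$feature_id[i]
    pp <- permutation_pass(y, genotypes, cand, feats$tss[i], n_perm = n_perm,
                           seed = seed + i, df_adjust = df_adjust,
                           adaptive = adaptive, adapt_min = adapt_min)
    rows[[length(rows) + 1]] <- tibble::tibble(
      feature_id = feats$feature_id[i], gene_id = feats$gene_id[i],
      n_candidates = length(cand),
      p_nominal_best = pp$p_nominal_best, best_variant_id = pp$best_variant_id,
      p_beta = pp$p_beta, p_direct = pp$p_direct,
      beta_shape1 = pp$beta_shape1, beta_shape2 = pp$beta_shape2,
      n_perm_used = pp$n_perm_used
    )
    noms[[length(noms) + 1]] <- nom
  }
  if (length(rows) == 0) abort("no feature had cis candidates")
  genes <- dplyr::bind_rows(rows)
  genes <- call_egenes(genes, fdr = fdr)
  list(genes = genes, nominal = dplyr::bind_rows(noms), skipped = skipped)
}
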