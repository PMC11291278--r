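# Per-group allele frequencies and U/R/C classification, Hudson F_ST
# (focal group vs pooled complement), group-wise negative-binomial
# differential expression, and the F_ST by DE-decile intersection.

#' Per-group allele frequencies and frequency classes
#'
#' AF is the mean dosage over 2 within each continental group; MAF is
#' `min(AF, 1 - AF)`. Classes follow the frequency-differentiation
#' convention: unobserved (U, MAF = 0), rare (R, 0 < MAF < 0.05), common
#' (C, MAF >= 0.05). Derived flags: `globally_common` (class C in every
#' group) and `unobserved_in_<G>` (class U in group G but present in at
#' least one other group).
#'
#' @param genotypes A [genotype_matrix()] (or a dosage matrix with
#'   variant ids as rownames).
#' @param samples Sample table aligned with the dosage columns.
#' @param rare_threshold MAF boundary between rare and common (default
#'   0.05).
#' @return A list: `af` (long tibble: variant_id, group, af, maf, class)
#'   and `flags` (wide tibble of per-variant logical flags).
#' @export
group_af <- function(genotypes, samples, rare_threshold = 0.05) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  samples <- as_sample_table(samples)
  groups <- unique(samples$continental_group)
  if (any(table(samples$continental_group) < 2)) abort("groups need >= 2 samples")
  vid <- rownames(dos) %||% sprintf("v%d", seq_len(nrow(dos)))
  af_m <- sapply(groups, function(g) {
    rowMeans(dos[, samples$continental_group == g, drop = FALSE]) / 2
  })
  maf_m <- pmin(af_m, 1 - af_m)
  class_m <- matrix("C", nrow(maf_m), ncol(maf_m), dimnames = dimnames(af_m))
  class_m[maf_m < rare_threshold] <- "R"
  class_m[maf_m == 0] <- "U"
  af <- tibble::tibble(
    variant_id = rep(vid, times = length(groups)),
    group = rep(groups, each = length(vid)),
    af = as.vector(af_m), maf = as.vector(maf_m),
    class = as.vector(class_m)
  )
  flags <- tibble::tibble(
    variant_id = vid,
    globally_common = apply(class_m == "C", 1, all)
  )
  present_somewhere <- rowSums(class_m != "U") > 0
  for (g in groups) {
    flags[[paste0("unobserved_in_", g)]] <-
      class_m[, g] == "U" & present_somewhere
  }
  if (all(c("EUR", "AFR") %in% groups)) {
    flags$unobserved_in_EUR_and_AFR <-
      class_m[, "EUR"] == "U" & class_m[, "AFR"] == "U" & present_somewhere
  }
  list(af = af, flags = flags)
}

#' Hudson F_ST estimator
#'
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                     {p_1(1-p_2) + p_2(1-p_1)}}
#' with `n` the number of sampled chromosomes. Negative estimates are
#' reported as-is; the value is `NA` when the denominator is zero (both
#' samples fixed for the same allele). Vectorized over all arguments.
#'
#' @param p1,p2 Sample allele frequencies in the two groups.
#' @param n1,n2 Chromosome sample sizes (>= 2).
#' @return Numeric vector of F_ST estimates.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

#' Focal-group F_ST for a set of variants
#'
#' For each variant and focal continental group, the Hudson F_ST between
#' the focal group and the pooled complement (all other samples).
#'
#' @param genotypes A [genotype_matrix()] or dosage matrix.
#' @param samples Sample table.
#' @param variant_ids Optional subset of variants (default all).
#' @return Tibble: `variant_id`, `focal_group`, `fst`.
#' @export
fst_focal <- function(genotypes, samples, variant_ids = NULL) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  samples <- as_sample_table(samples)
  if (!is.null(variant_ids)) {
    dos <- dos[match(variant_ids, rownames(dos)), , drop = FALSE]
  }
  groups <- unique(samples$continental_group)
  vid <- rownames(dos)
  out <- lapply(groups, function(g) {
    f_idx <- samples$continental_group == g
    p1 <- rowMeans(dos[, f_idx, drop = FALSE]) / 2
    p2 <- rowMeans(dos[, !f_idx, drop = FALSE]) / 2
    tibble::tibble(variant_id = vid, focal_group = g,
                   fst = hudson_fst(p1, 2 * sum(f_idx), p2, 2 * sum(!f_idx)))
  })
  dplyr::bind_rows(out)
}

#' Mean pairwise Hudson F_ST across groups
#'
#' Ratio-of-averages aggregate over variants for each group pair, then
#' averaged over pairs; a summary of overall differentiation.
#'
#' @inheritParams fst_focal
#' @return A single number.
#' @export
mean_pairwise_fst <- function(genotypes, samples) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  samples <- as_sample_table(samples)
  groups <- unique(samples$continental_group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  vals <- vapply(pairs, function(pr) {
    i1 <- samples$continental_group == pr[1]
    i2 <- samples$continental_group == pr[2]
    p1 <- rowMeans(dos[, i1, drop = FALSE]) / 2
    p2 <- rowMeans(dos[, i2, drop = FALSE]) / 2
    n1 <- 2 * sum(i1); n2 <- 2 * sum(i2)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)            # ratio of averages
  }, numeric(1))
  mean(vals)
}

#' Negative-binomial differential expression, focal group vs rest
#'
#' Per gene: NB GLM with log link and log size-factor offset, likelihood
#' ratio test of the focal-vs-rest indicator (per-gene dispersion by
#' maximum likelihood, method-of-moments fallback). Two-tailed p, BH
#' q-values, and p-rank deciles (10th = most significant).
#'
#' @param pheno Counts [phenotype_matrix()].
#' @param samples Sample table.
#' @param focal_group The continental group contrasted with all others.
#' @param size_factors Optional per-sample size factors (computed from
#'   the counts when NULL).
#' @return Tibble: `gene_id`, `focal_group`, `log2_fc`, `lrt_stat`, `p`,
#'   `q_value`, `de` (q <= 0.05), `decile`.
#' @export
nb_de <- function(pheno, samples, focal_group, size_factors = NULL) {
  stopifnot(inherits(pheno, "phenotype_matrix"), pheno$value_kind == "counts")
  samples <- as_sample_table(samples)
  if (is.null(size_factors)) {
    size_factors <- attr(normalize_expression(pheno), "size_factors")
  }
  counts <- pheno$values
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  focal <- as.numeric(samples$continental_group == focal_group)
  off <- log(size_factors)
  nll_fit <- function(y) {
    fit1 <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ focal + offset(off))),
      error = function(e) NULL)
    if (is.null(fit1)) {
      # method-of-moments dispersion fallback, then fixed-theta GLM
      mu <- pmax(mean(y / exp(off)), 1e-8) * exp(off)
      disp <- max((var(y / exp(off)) - mean(y / exp(off))) /
                    mean(y / exp(off))^2, 1e-4)
      theta <- 1 / disp
      fit1 <- suppressWarnings(glm(y ~ focal + offset(off),
                                   family = MASS::negative.binomial(theta)))
      theta_used <- theta
    } else {
      theta_used <- fit1$theta
    }
    fit0 <- suppressWarnings(glm(y ~ 1 + offset(off),
                                 family = MASS::negative.binomial(theta_used)))
    fit1f <- suppressWarnings(glm(y ~ focal + offset(off),
                                  family = MASS::negative.binomial(theta_used)))
    lrt <- fit0$deviance - fit1f$deviance
    c(lfc = unname(coef(fit1f)["focal"]) / log(2), lrt = lrt,
      p = pchisq(lrt, 1, lower.tail = FALSE))
  }
  res <- t(apply(counts, 1, nll_fit))
  out <- tibble::tibble(
    gene_id = rownames(counts), focal_group = focal_group,
    log2_fc = res[, "lfc"], lrt_stat = res[, "lrt"], p = res[, "p"]
  )
  out$q_value <- p.adjust(out$p, method = "BH")
  out$de <- out$q_value <= 0.05
  r <- rank(out$p, ties.method = "first")
  out$decile <- 11L - as.integer(ceiling(10 * r / nrow(out)))
  out
}

#' F_ST of lead eQTLs stratified by differential-expression decile
#'
#' Joins each gene's lead-eQTL focal-group F_ST with the gene's DE decile
#' (10th = most significant DE), reports the mean F_ST per decile, and a
#' two-tailed Mann-Whitney U test comparing lead F_ST of DE vs non-DE
#' genes.
#'
#' @param leads Tibble: `gene_id`, `variant_id` (lead per gene-level
#'   credible set), `focal_group`, `fst`.
#' @param de Result of [nb_de()] for the same focal group.
#' @return List: `deciles` tibble (decile, mean_fst, n), `u_test`
#'   (statistic, p_value), `joined` tibble.
#' @export
fst_by_de_decile <- function(leads, de) {
  j <- dplyr::inner_join(leads, de, by = c("gene_id", "focal_group"))
  if (nrow(j) < 10) abort("need at least 10 genes with DE and F_ST results")
  dec <- dplyr::summarise(dplyr::group_by(j, .data$decile),
                          mean_fst = mean(.data$fst, na.rm = TRUE),
                          n = dplyr::n(), .groups = "drop")
  wt <- if (length(unique(j$de)) == 2) {
    w <- wilcox.test(fst ~ de, data = j, exact = FALSE)
    tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value)
  } else {
    tibble::tibble(statistic = NA_real_, p_value = NA_real_)
  }
  list(deciles = dplyr::arrange(dec, .data$decile), u_test = wt, joined = j)
}
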