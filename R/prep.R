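# Phenotype preparation: size-factor normalization, rank-based inverse
# normal transform, covariate residualization, and expression PCs.

#' Normalize expression counts
#'
#' Median-of-ratios size factors against the geometric-mean pseudo-reference
#' (features with any zero count are excluded from factor estimation, as in
#' the standard bulk RNA-seq recipe), then `log2(count / size_factor + 1)`.
#'
#' @param pheno A [phenotype_matrix()] with `value_kind = "counts"`.
#' @return A [phenotype_matrix()] with `value_kind = "normalized"`; size
#'   factors are attached as the `size_factors` attribute.
#' @export
normalize_expression <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype_matrix"))
  if (pheno$value_kind != "counts") abort("normalize_expression expects counts")
  counts <- pheno$values
  if (any(colSums(counts) == 0)) abort("sample with all-zero counts")
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) abort("no feature free of zeros for size-factor estimation")
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(x) exp(median(log(x) - logref)))
  vals <- log2(sweep(counts, 2, sf, "/") + 1)
  out <- phenotype_matrix(pheno$features, vals, "normalized")
  attr(out, "size_factors") <- sf
  out
}

#' Rank-based inverse normal transform
#'
#' Per feature: \eqn{\Phi^{-1}((rank - 0.5)/n)} with average ranks for
#' ties. Constant features cannot be transformed; they are dropped and
#' reported via the `dropped_features` attribute.
#'
#' @param x A [phenotype_matrix()] or a numeric matrix (features x samples).
#' @return Same type as the input, transformed per feature; each retained
#'   row has mean ~0 and variance ~1.
#' @export
inverse_normal_transform <- function(x) {
  vals <- if (inherits(x, "phenotype_matrix")) x$values else as.matrix(x)
  keep <- apply(vals, 1, function(v) length(unique(v)) >= 2)
  dropped <- (rownames(vals) %||% sprintf("f%d", seq_len(nrow(vals))))[!keep]
  if (any(!keep)) {
    warn(sprintf("dropping %d constant feature(s)", sum(!keep)))
  }
  vals <- vals[keep, , drop = FALSE]
  n <- ncol(vals)
  out <- t(apply(vals, 1, function(v) qnorm((rank(v) - 0.5) / n)))
  dimnames(out) <- dimnames(vals)
  if (inherits(x, "phenotype_matrix")) {
    res <- phenotype_matrix(x$features[keep, ], out, "normalized")
    attr(res, "dropped_features") <- dropped
    res
  } else {
    attr(out, "dropped_features") <- dropped
    out
  }
}

#' Residualize phenotype values on covariates
#'
#' Ordinary-least-squares residuals per feature after projecting out an
#' intercept plus the supplied covariates. Residuals are orthogonal to
#' every covariate column; the operation is idempotent.
#'
#' @param values Numeric matrix, features x samples, or a
#'   [phenotype_matrix()].
#' @param covariates Numeric matrix, samples x covariates (no intercept
#'   column; one is added). May be `NULL` for centering only.
#' @return Residual matrix (or phenotype matrix) with an `n_covariates`
#'   attribute recording the residual degrees-of-freedom adjustment.
#' @export
residualize <- function(values, covariates = NULL) {
  is_pm <- inherits(values, "phenotype_matrix")
  vals <- if (is_pm) values$values else as.matrix(values)
  n <- ncol(vals)
  X <- cbind(intercept = rep(1, n), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("covariate design is rank-deficient")
  res <- t(qr.resid(qx, t(vals)))
  dimnames(res) <- dimnames(vals)
  k <- ncol(X) - 1L
  if (is_pm) {
    out <- phenotype_matrix(values$features, res, "normalized")
  } else {
    out <- res
  }
  attr(out, "n_covariates") <- k
  out
}

#' Expression principal components
#'
#' Sample-level PCs of the (feature-centered) normalized expression
#' matrix, used as hidden-factor covariates in QTL scans.
#'
#' @param pheno A [phenotype_matrix()] (normalized values) or matrix.
#' @param n_pcs Number of components (default 10, capped at what the data
#'   support).
#' @return Numeric matrix, samples x `n_pcs`, columns named `PC1`, ...
#' @export
expression_pcs <- function(pheno, n_pcs = 10) {
  vals <- if (inherits(pheno, "phenotype_matrix")) pheno$values else as.matrix(pheno)
  n_pcs <- min(n_pcs, nrow(vals) - 1L, ncol(vals) - 1L)
  pc <- prcomp(t(vals), center = TRUE, scale. = FALSE)
  m <- pc$x[, seq_len(n_pcs), drop = FALSE]
  colnames(m) <- paste0("PC", seq_len(n_pcs))
  m
}

#' Build the standard covariate design from sample metadata
#'
#' Batch indicator columns (first batch as reference), a sex indicator,
#' and optionally expression PCs.
#'
#' @param samples A sample table (see [as_sample_table()]).
#' @param pcs Optional samples x PCs matrix from [expression_pcs()].
#' @return Numeric matrix, samples x covariates.
#' @export
covariate_design <- function(samples, pcs = NULL) {
  samples <- as_sample_table(samples)
  batches <- sort(unique(samples$batch))
  out <- NULL
  if (length(batches) > 1) {
    b <- sapply(batches[-1], function(bb) as.numeric(samples$batch == bb))
    colnames(b) <- paste0("batch", batches[-1])
    out <- cbind(out, b)
  }
  out <- cbind(out, sex_M = as.numeric(samples$sex == "M"))
  if (!is.null(pcs)) out <- cbind(out, pcs)
  rownames(out) <- samples$sample_id
  out
}

#' Prepare phenotypes for QTL scanning
#'
#' Convenience wrapper: normalize counts (if needed), inverse-normal
#' transform each feature, and residualize on batch, sex and expression
#' PCs.
#'
#' @param pheno A [phenotype_matrix()] (counts, ratios or normalized).
#' @param samples Sample table aligned with `pheno` columns.
#' @param n_pcs Number of expression PCs to include (default 10).
#' @return A list with elements `pheno` (residualized phenotype matrix),
#'   `covariates` (samples x covariates design), and `size_factors`
#'   (NULL unless counts were normalized).
#' @export
prepare_phenotypes <- function(pheno, samples, n_pcs = 10) {
  samples <- as_sample_table(samples)
  stopifnot(identical(pheno$samples, samples$sample_id))
  sf <- NULL
  if (pheno$value_kind == "counts") {
    pheno <- normalize_expression(pheno)
    sf <- attr(pheno, "size_factors")
  }
  pcs <- if (n_pcs > 0) expression_pcs(pheno, n_pcs) else NULL
  covs <- covariate_design(samples, pcs)
  ready <- residualize(inverse_normal_transform(pheno), covs)
  list(pheno = ready, covariates = covs, size_factors = sf)
}
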