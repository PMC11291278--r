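# On-disk formats: VCF 4.x for genotypes (via vcfR), BED-like phenotype
# tables, and plain TSV for sample metadata / covariates. All writers emit
# uncompressed text so that write -> read -> write round-trips are stable.

#' Read genotypes from a VCF file
#'
#' Parses GT fields into a dosage matrix. Multiallelic records are skipped
#' (count reported via the `n_multiallelic_skipped` attribute). Missing
#' genotypes are imputed to the per-variant mean dosage rounded to the
#' nearest integer; variants with more than `max_missing` missingness are
#' excluded.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param sample_subset Optional character vector of sample ids to keep.
#' @param max_missing Maximum tolerated per-variant missing fraction
#'   (default 0.05).
#' @return A [genotype_matrix()], phased when all GT fields use `|`.
#' @export
read_vcf <- function(path, sample_subset = NULL, max_missing = 0.05) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2) abort("VCF has no genotype columns")
  samples <- colnames(gt_raw)[-1]
  if (!is.null(sample_subset)) {
    keep <- samples %in% sample_subset
    if (!any(keep)) abort("no samples overlap sample_subset")
    gt_raw <- gt_raw[, c(1L, which(keep) + 1L), drop = FALSE]
    samples <- samples[keep]
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    inform(sprintf("skipping %d multiallelic record(s)", n_multi))
    fix <- fix[!multi, , drop = FALSE]
    gt_raw <- gt_raw[!multi, , drop = FALSE]
  }
  fmt <- gt_raw[, 1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) abort("GT field absent from FORMAT")
  gt <- gt_raw[, -1, drop = FALSE]
  if (any(gt_idx != 1L)) {
    for (i in which(gt_idx != 1L)) {
      gt[i, ] <- vapply(strsplit(gt[i, ], ":", fixed = TRUE),
                        function(x) x[gt_idx[i]], character(1))
    }
  } else if (any(grepl(":", gt, fixed = TRUE))) {
    gt <- sub(":.*$", "", gt)
  }
  phased <- all(grepl("|", gt, fixed = TRUE))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  h1 <- matrix(match(a1, c("0", "1")) - 1L, nrow = nrow(gt))
  h2 <- matrix(match(a2, c("0", "1")) - 1L, nrow = nrow(gt))
  dos <- h1 + h2
  miss_frac <- rowMeans(is.na(dos))
  keep_var <- miss_frac <= max_missing
  n_dropped <- sum(!keep_var)
  if (n_dropped > 0) {
    inform(sprintf("excluding %d variant(s) with > %.0f%% missing genotypes",
                   n_dropped, 100 * max_missing))
  }
  fix <- fix[keep_var, , drop = FALSE]
  dos <- dos[keep_var, , drop = FALSE]
  h1 <- h1[keep_var, , drop = FALSE]
  h2 <- h2[keep_var, , drop = FALSE]
  n_imputed <- 0L
  for (i in which(rowSums(is.na(dos)) > 0)) {
    na <- is.na(dos[i, ])
    fill <- as.integer(round(mean(dos[i, !na])))
    dos[i, na] <- fill
    n_imputed <- n_imputed + sum(na)
    phased <- FALSE
  }
  colnames(dos) <- samples
  variants <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = "_"),
                        fix$ID)
  )
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  dos <- dos[ord, , drop = FALSE]
  haps <- NULL
  if (phased) {
    h1 <- h1[ord, , drop = FALSE]; h2 <- h2[ord, , drop = FALSE]
    colnames(h1) <- colnames(h2) <- samples
    haps <- list(hap1 = h1, hap2 = h2)
  }
  g <- genotype_matrix(variants, dos, haps)
  attr(g, "n_multiallelic_skipped") <- n_multi
  attr(g, "n_imputed_genotypes") <- n_imputed
  attr(g, "n_high_missing_dropped") <- n_dropped
  g
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotype fields. Phased `|`
#' separators are used when haplotypes are present.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  if (!is.null(geno$haplotypes)) {
    gt <- matrix(paste0(geno$haplotypes$hap1, "|", geno$haplotypes$hap2),
                 nrow = nrow(v))
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[geno$dosages + 1L], nrow = nrow(v))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=divqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype BED file
#'
#' Tab-delimited with four annotation columns (`chrom`, `start`, `end`,
#' `feature_id`) followed by one column per sample. On-disk coordinates are
#' 0-based half-open (BED); the stored TSS is `start + 1` (1-based).
#' Feature ids of the form `gene:cluster:intron` carry the gene and
#' splicing-cluster labels; plain ids are treated as gene-level features.
#'
#' @param path Path to the BED-like phenotype file.
#' @param value_kind Passed to [phenotype_matrix()] (default `"counts"`).
#' @return A [phenotype_matrix()].
#' @export
read_phenotype_bed <- function(path, value_kind = "counts") {
  if (!file.exists(path)) abort(paste("no such file:", path))
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  names(x) <- sub("^#", "", hdr)
  samples <- names(x)[-(1:4)]
  if (anyDuplicated(x[[4]]) > 0) abort("duplicate feature_id in phenotype BED")
  vals <- matrix(NA_real_, nrow(x), length(samples),
                 dimnames = list(x[[4]], samples))
  for (j in seq_along(samples)) {
    col <- x[[j + 4]]
    bad <- is.na(col) | is.na(suppressWarnings(as.numeric(col)))
    if (any(bad)) {
      abort(sprintf("non-numeric value for feature '%s', sample '%s'",
                    x[[4]][which(bad)[1]], samples[j]))
    }
    vals[, j] <- as.numeric(col)
  }
  parts <- strsplit(x[[4]], ":", fixed = TRUE)
  gene_id <- vapply(parts, `[`, character(1), 1)
  cluster_id <- vapply(parts, function(p) if (length(p) >= 3) p[2] else NA_character_,
                       character(1))
  features <- tibble::tibble(
    feature_id = x[[4]],
    gene_id = gene_id,
    chrom = x[[1]],
    tss = as.integer(x[[2]]) + 1L,
    strand = "+",
    cluster_id = cluster_id
  )
  phenotype_matrix(features, vals, value_kind)
}

#' Write a phenotype BED file
#'
#' Inverse of [read_phenotype_bed()]: the stored 1-based TSS becomes the
#' 0-based BED `start`, with `end = start + 1`.
#'
#' @param pheno A [phenotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_bed <- function(pheno, path) {
  f <- pheno$features
  vals <- apply(pheno$values, c(1, 2), function(x) sprintf("%.17g", x))
  header <- paste(c("#chrom", "start", "end", "feature_id", pheno$samples),
                  collapse = "\t")
  body <- paste(f$chrom, f$tss - 1L, f$tss, f$feature_id,
                apply(vals, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' @param path TSV with columns `sample_id`, `population`,
#'   `continental_group`, `sex`, `batch`.
#' @return A validated sample table (see [as_sample_table()]).
#' @export
read_sample_table <- function(path) {
  as_sample_table(readr::read_tsv(path, col_types = "cccci", progress = FALSE))
}

#' Write a sample metadata TSV
#' @param samples A sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read a covariate TSV
#'
#' On disk: one row per covariate, first column `covariate`, then one
#' column per sample. Returned as a samples x covariates numeric matrix
#' (the design-matrix orientation used by the modelling stages).
#'
#' @param path Input path.
#' @return Numeric matrix, samples in rows.
#' @export
read_covariates <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    covariate = "c", .default = "d"), progress = FALSE)
  m <- t(as.matrix(x[, -1]))
  colnames(m) <- x$covariate
  m
}

#' Write a covariate TSV
#' @param covariates Numeric matrix, samples in rows, covariates in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  x <- tibble::as_tibble(t(covariates), .name_repair = "minimal")
  x <- tibble::add_column(x, covariate = colnames(covariates), .before = 1)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
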