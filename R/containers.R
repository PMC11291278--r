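# Lightweight S3 containers shared by all stages. Matrices keep samples in
# columns (features/variants in rows); result tables are tibbles.

#' Construct a genotype matrix object
#'
#' Bundles biallelic variant metadata with a dosage matrix (variants x
#' samples, values in 0/1/2) and, optionally, phased haplotypes.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `variant_id`. Must be sorted by (chrom, pos).
#' @param dosages Integer matrix, `nrow(variants)` x n_samples; column
#'   names are sample ids.
#' @param haplotypes Optional list of two 0/1 matrices (`hap1`, `hap2`) of
#'   the same dimension as `dosages`; their sum must equal `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, dosages, haplotypes = NULL) {
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "variant_id") %in% names(variants)))
  if (anyDuplicated(variants$variant_id) > 0) {
    abort("duplicate variant_id in genotype matrix")
  }
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    abort("variants must be sorted by (chrom, pos)")
  }
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(variants)) {
    abort("dosage rows must match variants")
  }
  if (!all(dosages %in% 0:2)) abort("dosages must be in {0, 1, 2}")
  rownames(dosages) <- variants$variant_id
  if (!is.null(haplotypes)) {
    stopifnot(is.list(haplotypes), length(haplotypes) == 2)
    h <- haplotypes[[1]] + haplotypes[[2]]
    if (!isTRUE(all(h == dosages))) {
      abort("haplotype sum must equal dosage")
    }
  }
  structure(
    list(variants = variants, dosages = dosages, haplotypes = haplotypes,
         samples = colnames(dosages)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d samples%s\n",
              nrow(x$dosages), ncol(x$dosages),
              if (!is.null(x$haplotypes)) " (phased)" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Construct a phenotype matrix object
#'
#' @param features Tibble with columns `feature_id`, `gene_id`, `chrom`,
#'   `tss` (1-based), `strand`, and optionally `cluster_id` (introns).
#' @param values Numeric matrix, features x samples, column names are
#'   sample ids.
#' @param value_kind One of `"counts"`, `"normalized"`, `"ratios"`.
#' @return An object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(features, values,
                             value_kind = c("counts", "normalized", "ratios")) {
  value_kind <- match.arg(value_kind)
  features <- tibble::as_tibble(features)
  stopifnot(all(c("feature_id", "gene_id", "chrom", "tss") %in% names(features)))
  if (!"strand" %in% names(features)) features$strand <- "+"
  if (!"cluster_id" %in% names(features)) features$cluster_id <- NA_character_
  if (anyDuplicated(features$feature_id) > 0) abort("duplicate feature_id")
  if (anyNA(features$tss)) abort("tss must be defined for every feature")
  values <- as.matrix(values)
  if (nrow(values) != nrow(features)) abort("value rows must match features")
  if (value_kind == "counts" && any(values < 0)) abort("counts must be non-negative")
  if (value_kind == "ratios" && (any(values < 0) || any(values > 1))) {
    abort("ratios must lie in [0, 1]")
  }
  rownames(values) <- features$feature_id
  structure(
    list(features = features, values = values, value_kind = value_kind,
         samples = colnames(values)),
    class = "phenotype_matrix"
  )
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("<phenotype_matrix:%s> %d features x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.phenotype_matrix <- function(x) dim(x$values)

#' Validate a sample metadata table
#'
#' Checks the invariants of the cohort design: unique sample ids, complete
#' fields, and each population nested in exactly one continental group.
#'
#' @param x Data frame with columns `sample_id`, `population`,
#'   `continental_group`, `sex` (`"F"`/`"M"`), `batch`.
#' @return The validated table as a tibble.
#' @export
as_sample_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("sample_id", "population", "continental_group", "sex", "batch")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("sample table missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(x$sample_id) > 0) abort("sample_id values must be unique")
  if (!all(complete.cases(x[need]))) abort("sample table fields must be non-missing")
  if (!all(x$sex %in% c("F", "M"))) abort("sex must be 'F' or 'M'")
  nest <- unique(x[, c("population", "continental_group")])
  if (anyDuplicated(nest$population) > 0) {
    abort("each population must map to exactly one continental group")
  }
  x$batch <- as.integer(x$batch)
  x
}
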