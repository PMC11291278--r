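# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

# a balanced cohort: n_groups x pops_per_group x m samples
cohort <- function(n_groups = 2, pops_per_group = 2, m = 10, n_batches = 2,
                   seed = 1) {
  set.seed(seed)
  groups <- if (n_groups <= 5) c("AFR", "AMR", "EAS", "EUR", "SAS")[seq_len(n_groups)]
            else sprintf("G%02d", seq_len(n_groups))
  pops <- unlist(lapply(groups, function(g) paste0(g, "_p", seq_len(pops_per_group))))
  n <- length(pops) * m
  as_sample_table(tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = rep(pops, each = m),
    continental_group = rep(rep(groups, each = pops_per_group), each = m),
    sex = sample(c("F", "M"), n, replace = TRUE),
    batch = rep_len(seq_len(n_batches), n)
  ))
}

# a tiny genotype matrix with chosen positions and dosage rows
toy_genotypes <- function(pos, dosages, chrom = "chr1") {
  dosages <- as.matrix(dosages)
  colnames(dosages) <- sprintf("S%03d", seq_len(ncol(dosages)))
  genotype_matrix(
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
                   variant_id = sprintf("%s_%d_A_G", chrom, pos)),
    dosages)
}

# default small study config used across tests (n = 500 where power matters)
study_config <- function(seed, n_genes = 20, samples_per_population = 50,
                         ...) {
  sim_config(n_genes = n_genes, seed = seed, populations_per_group = 2,
             samples_per_population = samples_per_population,
             n_groups = 5, ...)
}

# hand-written 3-variant, 4-sample VCF (one extra multiallelic record)
write_fixture_vcf <- function(path, multiallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", "A2", "A3", "A4", sep = "\t"),
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0\t1/1",
    "chr1\t300\tv3\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1\t0/1")
  if (multiallelic) {
    lines <- c(lines,
               "chr1\t400\tv4\tG\tA,T\t.\tPASS\t.\tGT\t1/2\t0/0\t0/1\t0/2")
  }
  writeLines(lines, path)
  path
}
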