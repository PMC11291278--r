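test_that("zero differentiation collapses to the ancestral frequency", {
  cfg <- study_config(seed = 1, n_genes = 2, samples_per_population = 5,
                      f_group = 0, f_pop = 0)
  cfg$variants_per_cis_window <- 25
  g <- simulate_genotypes(cfg)
  af <- attr(g, "af")
  for (grp in c("AFR", "AMR", "EAS", "EUR", "SAS")) {
    expect_equal(af[[grp]], af$ancestral_p)
  }
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- study_config(seed = 77, n_genes = 3, samples_per_population = 5)
  cfg$variants_per_cis_window <- 15
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$splicing$values, s2$splicing$values)
  expect_identical(s1$truth$causal, s2$truth$causal)
})

test_that("group differentiation matches the Balding-Nichols target", {
  cfg <- sim_config(n_genes = 10, seed = 5, n_groups = 2,
                    populations_per_group = 1, samples_per_population = 100,
                    variants_per_cis_window = 200, f_pop = 0)
  g <- simulate_genotypes(cfg)
  fst <- mean_pairwise_fst(g, attr(g, "samples"))
  expect_gt(fst, 0.08)
  expect_lt(fst, 0.12)
})

test_that("truth-table variants exist in the emitted study and files load back", {
  cfg <- study_config(seed = 6, n_genes = 5, samples_per_population = 5)
  cfg$variants_per_cis_window <- 30
  sim <- simulate_study(cfg)
  expect_true(all(sim$truth$causal$variant_id %in% sim$genotypes$variants$variant_id))
  expect_true(all(abs(sim$truth$causal$log2_afc) >= cfg$log2_afc_range[1]))
  expect_true(all(abs(sim$truth$causal$log2_afc) <= cfg$log2_afc_range[2]))
  # interaction_fraction = 0 by default: no gene carries a true interaction
  expect_true(all(sim$truth$genes$interaction_delta == 0))

  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  geno <- read_vcf(file.path(dir, "genotypes.vcf"))
  expr <- read_phenotype_bed(file.path(dir, "expression.bed"))
  st <- read_sample_table(file.path(dir, "samples.tsv"))
  expect_identical(unname(geno$dosages), unname(sim$genotypes$dosages))
  expect_equal(unname(expr$values), unname(sim$expression$values))
  expect_equal(st, sim$samples)
})

test_that("expression follows the aFC generative model", {
  # single causal beta = 1: mean of the alt/alt class is ~2x the ref/ref
  # class on the haplotype-average scale, with noise switched off
  cfg <- study_config(seed = 9, n_genes = 1, samples_per_population = 60,
                      causal_prob = c(0, 1, 0, 0), noise_sd_log2 = 0,
                      batch_effect_sd = 0, log2_afc_range = c(1, 1),
                      library_size_range = c(1, 1),
                      base_mean_range = c(4096, 4096))
  cfg$variants_per_cis_window <- 10
  sim <- simulate_study(cfg, splicing = FALSE)
  cz <- sim$truth$causal
  expect_equal(nrow(cz), 1L)
  g <- sim$genotypes$dosages[cz$variant_row, ]
  y <- sim$expression$values[1, ]
  ratio <- mean(y[g == 2]) / mean(y[g == 0])
  expect_equal(ratio, 2^cz$log2_afc, tolerance = 0.05)
  # heterozygotes sit at the haplotype average (1 + k)/2
  expect_equal(mean(y[g == 1]) / mean(y[g == 0]), (1 + 2^cz$log2_afc) / 2,
               tolerance = 0.05)
})

test_that("beta = 0 genes are independent of genotype", {
  cfg <- study_config(seed = 10, n_genes = 10, samples_per_population = 30,
                      causal_prob = c(1, 0, 0, 0))
  cfg$variants_per_cis_window <- 20
  sim <- simulate_study(cfg, splicing = FALSE)
  vals <- residualize(inverse_normal_transform(log2(sim$expression$values + 1)),
                      covariate_design(sim$samples))
  slopes <- sapply(seq_len(10), function(i) {
    g <- sim$genotypes$dosages[(i - 1) * 20 + 7, ]
    if (length(unique(g)) < 2) return(NA)
    f <- summary(lm(vals[i, ] ~ g))
    f$coefficients[2, 4]
  })
  expect_gt(min(slopes, na.rm = TRUE), 1e-4)   # no spurious strong hit
})

test_that("splicing ratios are Dirichlet-normalized and sQTL shifts the target intron", {
  cfg <- study_config(seed = 11, n_genes = 8, samples_per_population = 30,
                      causal_prob = c(0, 1, 0, 0), log2_afc_range = c(1.5, 1.5))
  cfg$variants_per_cis_window <- 20
  sim <- simulate_study(cfg)
  spl <- sim$splicing
  sums <- rowsum(spl$values, spl$features$cluster_id)
  expect_equal(unname(sums), matrix(1, nrow(sums), ncol(sums)), tolerance = 1e-12)
  tr <- sim$truth$splicing
  with_qtl <- tr[!is.na(tr$sqtl_variant), ]
  expect_gt(nrow(with_qtl), 0)
  # the shifted intron's ratio correlates with dosage in the shift direction
  cors <- sapply(seq_len(nrow(with_qtl)), function(i) {
    row <- match(with_qtl$target_intron[i], spl$features$feature_id)
    v <- match(with_qtl$sqtl_variant[i], sim$genotypes$variants$variant_id)
    cor(spl$values[row, ], sim$genotypes$dosages[v, ]) * sign(with_qtl$log2_shift[i])
  })
  expect_gt(mean(cors > 0), 0.8)
})

test_that("structured phenotypes hit their variance-fraction target", {
  st <- cohort(n_groups = 5, pops_per_group = 2, m = 20)
  ph <- simulate_structured_phenotypes(st, 50, var_frac_group = 0.02,
                                       var_frac_population = 0.10, seed = 4)
  tr <- attr(ph, "truth")
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$var_frac_population == 0.10))
  expect_true(all(tr$var_frac_group >= 0 & tr$var_frac_group <= 0.10 + 1e-9))
})
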