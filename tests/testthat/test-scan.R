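test_that("the cis window is 1 Mb inclusive on both ends", {
  set.seed(1)
  dos <- matrix(rbinom(3 * 40, 2, 0.4), nrow = 3)
  g <- toy_genotypes(c(999999L, 1000000L, 3000000L), dos)
  idx <- cis_candidates(g, "chr1", tss = 2000000L, maf_min = 0)
  expect_equal(g$variants$pos[idx], c(1000000L, 3000000L))
  expect_false(999999L %in% g$variants$pos[idx])
})

test_that("the MAF floor removes rare candidates", {
  n <- 200
  set.seed(2)
  mafs <- c(0.001, 0.002, 0.004, 0.05, 0.1, 0.2, 0.3, 0.4, 0.45, 0.25)
  dos <- t(sapply(mafs, function(m) rbinom(n, 2, m)))
  # force the three rare ones below 1% realized MAF
  dos[1:3, ] <- 0; dos[1, 1] <- 1; dos[2, 1] <- 1; dos[3, 1] <- 1
  g <- toy_genotypes(seq(1e6, 1e6 + 9000, by = 1000), dos)
  idx <- cis_candidates(g, "chr1", tss = 1e6, maf_min = 0.01)
  expect_equal(length(idx), 7L)
})

test_that("nominal scan handles the null and degenerate extremes", {
  set.seed(3)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  y_orth <- residualize(matrix(rnorm(n), 1), matrix(g, ncol = 1))[1, ]
  gm <- toy_genotypes(1e6, matrix(g, nrow = 1))
  res <- nominal_scan(y_orth, gm, 1L, tss = 1e6)
  expect_lt(abs(res$slope), 1e-10)
  expect_gt(res$p, 0.999)

  res2 <- nominal_scan(as.numeric(g), gm, 1L, tss = 1e6)
  expect_lt(res2$p, 1e-30)
  expect_equal(res2$slope, 1)

  # affine transforms of the phenotype leave t and p unchanged
  y <- rnorm(n)
  r1 <- nominal_scan(y, gm, 1L, tss = 1e6)
  r2 <- nominal_scan(3 * y - 7, gm, 1L, tss = 1e6)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)

  g0 <- toy_genotypes(1e6, matrix(0L, 1, n))
  expect_error(nominal_scan(y, g0, 1L, tss = 1e6), "monomorphic")
})

test_that("a best hit beating all permutations attains the direct-p bound", {
  set.seed(4)
  n <- 100
  dos <- matrix(rbinom(20 * n, 2, 0.3), nrow = 20)
  g <- toy_genotypes(seq(1e6, by = 1000, length.out = 20), dos)
  y <- dos[5, ] + rnorm(n, 0, 0.05)
  pp <- permutation_pass(y, g, seq_len(20), tss = 1e6, n_perm = 100, seed = 1)
  expect_equal(pp$p_direct, 1 / 101)
  expect_equal(pp$best_variant_id, g$variants$variant_id[5])
  expect_lt(pp$p_beta, 0.01)
})

test_that("gene-level empirical p is monotone in the best nominal p", {
  # with the Beta parameters held fixed, pbeta is non-decreasing
  shape <- c(1.2, 40)
  ps <- sort(runif(50))
  expect_true(all(diff(pbeta(ps, shape[1], shape[2])) >= 0))
})

test_that("BH eGene calling follows the arithmetic", {
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:100),
                          p_beta = c(rep(0.001, 10), rep(0.9, 90)))
  called <- call_egenes(genes, fdr = 0.05)
  expect_equal(sum(called$is_egene), 10L)
  expect_true(all(called$is_egene[1:10]))

  none <- call_egenes(tibble::tibble(gene_id = "g", p_beta = 1))
  expect_equal(sum(none$is_egene), 0L)
  expect_error(call_egenes(genes[0, ]), "empty")
})

test_that("the scan finds planted signals genome-wide at 5% FDR", {
  cfg <- study_config(seed = 21, n_genes = 12, samples_per_population = 30,
                      causal_prob = c(0.5, 0.5, 0, 0),
                      log2_afc_range = c(1, 2))
  cfg$variants_per_cis_window <- 40
  sim <- simulate_study(cfg, splicing = FALSE)
  prep <- prepare_phenotypes(sim$expression, sim$samples, n_pcs = 3)
  sc <- scan_study(prep$pheno, sim$genotypes, n_perm = 200, seed = 2)
  true_e <- sim$truth$genes$gene_id[sim$truth$genes$n_causal > 0]
  expect_gt(mean(sc$genes$is_egene[sc$genes$gene_id %in% true_e]), 0.7)
  expect_lt(mean(sc$genes$is_egene[!sc$genes$gene_id %in% true_e]), 0.5)
})
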