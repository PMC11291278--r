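test_that("eligibility requires MAF >= 0.05 in at least two groups", {
  af <- tibble::tibble(
    variant_id = rep(c("a", "b"), each = 5),
    group = rep(c("G1", "G2", "G3", "G4", "G5"), 2),
    maf = c(0.10, 0.06, 0.01, 0.0, 0.0,
            0.10, 0.01, 0.01, 0.0, 0.0))
  el <- eligibility_filter(af)
  expect_true(el$eligible[el$variant_id == "a"])
  expect_false(el$eligible[el$variant_id == "b"])
})

test_that("eligibility counts match enumeration on a random fixture", {
  st <- cohort(n_groups = 5, pops_per_group = 1, m = 20)
  set.seed(1)
  dos <- matrix(rbinom(300 * nrow(st), 2, runif(300, 0.01, 0.5)), nrow = 300)
  rownames(dos) <- sprintf("v%03d", 1:300)
  ga <- group_af(dos, st)
  el <- eligibility_filter(ga$af)
  # brute-force enumeration
  want <- sapply(rownames(dos), function(v) {
    n_pass <- 0
    for (g in unique(st$continental_group)) {
      af <- mean(dos[v, st$continental_group == g]) / 2
      if (min(af, 1 - af) >= 0.05) n_pass <- n_pass + 1
    }
    n_pass >= 2
  })
  expect_equal(el$eligible[match(rownames(dos), el$variant_id)], unname(want))
})

test_that("the multi-causal test with one lead equals the single test", {
  st <- cohort(n_groups = 3, pops_per_group = 2, m = 25)
  set.seed(2)
  n <- nrow(st)
  g <- rbinom(n, 2, 0.3)
  covs <- covariate_design(st)
  y <- 0.5 * g + rnorm(n)
  r1 <- interaction_test_single(y, g, st, covs)
  r2 <- interaction_test_multi(y, matrix(g, ncol = 1), 1, st, covs)
  expect_equal(r1$f, r2$f, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(r1$df1, r2$df1)
})

test_that("degenerate designs are refused", {
  st <- cohort(n_groups = 1, pops_per_group = 2, m = 20)
  set.seed(3)
  n <- nrow(st)
  g <- rbinom(n, 2, 0.4)
  y <- rnorm(n)
  expect_error(interaction_test_single(y, g, st), "fewer than two")

  # variant monomorphic outside one group: no interaction df either
  st2 <- cohort(n_groups = 2, pops_per_group = 1, m = 20)
  g2 <- c(rbinom(20, 2, 0.4), rep(0, 20))
  expect_error(interaction_test_single(rnorm(40), g2, st2), "fewer than two")
})

test_that("PC interaction equals the categorical test when PCs recode groups", {
  st <- cohort(n_groups = 2, pops_per_group = 1, m = 40)
  set.seed(4)
  n <- nrow(st)
  g <- rbinom(n, 2, 0.4)
  y <- 0.4 * g + 0.3 * (st$continental_group == "AMR") + rnorm(n)
  pc <- matrix(as.numeric(st$continental_group == "AMR"), ncol = 1)
  r_cat <- interaction_test_single(y, g, st, min_group_n = 2)
  r_pc <- interaction_test_pcs(y, g, pc)
  expect_equal(r_pc$p, r_cat$p, tolerance = 1e-8)
})

test_that("a true interaction is detected by both models", {
  st <- cohort(n_groups = 5, pops_per_group = 2, m = 50)
  set.seed(5)
  n <- nrow(st)
  hits <- replicate(10, {
    g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.3)
    delta <- 0.5 * (st$continental_group == "EAS")
    # residual noise at the generator default (0.5 on the log2 scale)
    y <- 0.5 * g1 + 0.3 * g2 + delta * g1 + rnorm(n, 0, 0.5)
    c(interaction_test_single(y, g1, st)$p,
      interaction_test_multi(y, cbind(a = g1, b = g2), 1, st)$p)
  })
  expect_gte(mean(hits[1, ] < 2.5e-4), 0.8)   # Bonferroni alpha for 200 tests
  expect_gte(mean(hits[2, ] < 2.5e-4), 0.8)
})

test_that("Bonferroni summary counts and stratifies correctly", {
  res <- tibble::tibble(
    model = rep("single", 100),
    p = c(rep(1e-6, 3), runif(97, 0.2, 1)),
    n_credible_sets = rep(c(1, 2), 50))
  bs <- bonferroni_summary(res, alpha = 0.05)
  expect_equal(bs$counts$n_significant, 3L)
  expect_equal(sum(bs$strata$n_significant), 3L)

  none <- bonferroni_summary(tibble::tibble(model = "m", p = rep(1, 100)))
  expect_equal(none$counts$n_significant, 0L)
})
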