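test_that("exact model data give the exact solution and the cap binds", {
  g <- rep(c(0, 1, 2), each = 20)
  y <- 1 * ((2 - g) + g * 2) / 2          # C = 1, k = 2
  a <- afc_single(y, g)
  expect_equal(a$log2_afc, 1, tolerance = 1e-6)
  expect_false(a$capped)

  y2 <- c(rep(1, 20), rep(200.5, 20), rep(400, 20))   # 400-fold, beyond cap
  a2 <- afc_single(y2, g)
  expect_equal(a2$log2_afc, log2(100), tolerance = 1e-4)
  expect_true(a2$capped)

  expect_error(afc_single(y, rep(1, 60)), "monomorphic")
})

test_that("a null variant estimates ~0 at n = 500", {
  set.seed(1)
  n <- 500
  ests <- sapply(1:15, function(r) {
    g <- rbinom(n, 2, 0.3)
    y <- 2^(rnorm(n, 5, 0.5))
    afc_single(y, g, n_boot = 0)$log2_afc
  })
  expect_lt(median(abs(ests)), 0.05)
})

test_that("scale equivariance and allele-flip antisymmetry hold", {
  set.seed(2)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  y <- ((2 - g) + g * 2^0.7) / 2 * 2^rnorm(n, 0, 0.3)
  a1 <- afc_single(y, g)
  a2 <- afc_single(y * 37.5, g)
  expect_equal(a1$log2_afc, a2$log2_afc, tolerance = 1e-8)
  a3 <- afc_single(y, 2 - g)
  expect_equal(a3$log2_afc, -a1$log2_afc, tolerance = 1e-6)
})

test_that("the joint model reduces to the marginal for one lead", {
  set.seed(3)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  y <- ((2 - g) + g * 2^1.1) / 2 * 2^rnorm(n, 0, 0.4)
  single <- afc_single(y, g)
  joint <- afc_conditional(y, matrix(g, ncol = 1), n_boot = 0)
  expect_equal(single$log2_afc, joint$log2_afc, tolerance = 1e-8)
})

test_that("collinear leads are dropped and flagged", {
  set.seed(4)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  y <- ((2 - g) + g * 2) / 2 * 2^rnorm(n, 0, 0.2)
  expect_warning(
    out <- afc_conditional(y, cbind(a = g, b = g), n_boot = 0),
    "collinear")
  expect_true(out$dropped_collinear[out$lead_variant_id == "b"])
  expect_false(out$dropped_collinear[out$lead_variant_id == "a"])
})

test_that("marginal-only modelling is biased when a second causal variant is
           frequency-linked; the joint model removes the bias", {
  set.seed(5)
  n <- 600
  bias_marg <- bias_joint <- numeric(20)
  for (r in 1:20) {
    # two variants whose dosages covary (shared structure)
    f <- rbinom(n, 1, 0.5)
    g1 <- rbinom(n, 2, 0.25 + 0.4 * f)
    g2 <- rbinom(n, 2, 0.25 + 0.4 * f)
    k1 <- 2^1; k2 <- 2^0.8
    mu <- ((2 - g1) + g1 * k1) / 2 * ((2 - g2) + g2 * k2) / 2
    y <- mu * 2^rnorm(n, 0, 0.3)
    bias_marg[r] <- afc_single(y, g1)$log2_afc - 1
    joint <- afc_conditional(y, cbind(v1 = g1, v2 = g2), n_boot = 0)
    bias_joint[r] <- joint$log2_afc[joint$lead_variant_id == "v1"] - 1
  }
  expect_gt(median(abs(bias_marg)) / median(abs(bias_joint)), 2)
})

test_that("the phased model matches the dosage model for a single lead", {
  set.seed(6)
  n <- 300
  h1 <- rbinom(n, 1, 0.3); h2 <- rbinom(n, 1, 0.3)
  g <- h1 + h2
  y <- (2^(1.2 * h1) + 2^(1.2 * h2)) / 2 * 2^rnorm(n, 0, 0.3)
  d <- afc_conditional(y, matrix(g, ncol = 1), n_boot = 0)
  p <- afc_conditional(y, matrix(g, ncol = 1), n_boot = 0,
                       haplotypes = list(matrix(h1, ncol = 1),
                                         matrix(h2, ncol = 1)))
  expect_equal(d$log2_afc, p$log2_afc, tolerance = 0.05)
  expect_equal(p$log2_afc, 1.2, tolerance = 0.15)
})

test_that("bootstrap standard errors are returned and positive", {
  set.seed(7)
  n <- 150
  g <- rbinom(n, 2, 0.4)
  y <- ((2 - g) + g * 2) / 2 * 2^rnorm(n, 0, 0.4)
  a <- afc_single(y, g, n_boot = 50)
  expect_gt(a$se, 0)
  expect_lt(a$se, 1)
})
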