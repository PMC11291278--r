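test_that("U/R/C classes follow the MAF thresholds exactly", {
  st <- cohort(n_groups = 2, pops_per_group = 1, m = 10)
  dos <- rbind(
    u = c(rep(0L, 10), rep(1L, 10)),            # AF 0 in AFR, 0.5 in AMR
    r = c(rep(0L, 9), 1L, rep(1L, 10)),         # AF 0.05 rare-boundary
    c = c(rep(1L, 10), rep(0L, 5), rep(1L, 5))) # common in both groups
  rownames(dos) <- c("u", "r", "c")
  ga <- group_af(dos, st)
  cls <- function(v, g) ga$af$class[ga$af$variant_id == v & ga$af$group == g]
  expect_equal(cls("u", "AFR"), "U")
  expect_equal(cls("r", "AFR"), "C")   # MAF exactly 0.05 is common
  expect_equal(cls("c", "AFR"), "C")
  expect_true(ga$flags$unobserved_in_AFR[ga$flags$variant_id == "u"])
  expect_false(ga$flags$globally_common[ga$flags$variant_id == "u"])
  expect_true(ga$flags$globally_common[ga$flags$variant_id == "c"])
})

test_that("classes on a 5-group fixture match exhaustive enumeration", {
  st <- cohort(n_groups = 5, pops_per_group = 1, m = 20)
  set.seed(1)
  dos <- matrix(rbinom(200 * nrow(st), 2, runif(200, 0, 0.5)), nrow = 200)
  rownames(dos) <- sprintf("v%03d", 1:200)
  ga <- group_af(dos, st)
  for (g in unique(st$continental_group)) {
    idx <- st$continental_group == g
    af <- rowMeans(dos[, idx]) / 2
    maf <- pmin(af, 1 - af)
    want <- ifelse(maf == 0, "U", ifelse(maf < 0.05, "R", "C"))
    got <- ga$af$class[ga$af$group == g][match(rownames(dos),
                                               ga$af$variant_id[ga$af$group == g])]
    expect_equal(got, unname(want))
  }
})

test_that("hudson_fst matches an independent formula implementation", {
  set.seed(2)
  p1 <- runif(500); p2 <- runif(500)
  n1 <- sample(10:500, 500, TRUE); n2 <- sample(10:500, 500, TRUE)
  oracle <- mapply(function(a, na, b, nb) {
    num <- (a - b)^2 - a * (1 - a) / (na - 1) - b * (1 - b) / (nb - 1)
    den <- a * (1 - b) + b * (1 - a)
    if (den == 0) NA_real_ else num / den
  }, p1, n1, p2, n2)
  expect_equal(hudson_fst(p1, n1, p2, n2), oracle, tolerance = 1e-12)

  expect_equal(hudson_fst(1, 100, 0, 100), 1)
  expect_true(is.na(hudson_fst(0, 50, 0, 50)))
  expect_lt(abs(hudson_fst(0.5, 100, 0.5, 100)), 0.02)
  expect_error(hudson_fst(0.5, 1, 0.5, 100))
})

test_that("negative-binomial DE detects a 2-fold focal shift and is calibrated", {
  st <- cohort(n_groups = 5, pops_per_group = 1, m = 30)
  n <- nrow(st)
  set.seed(3)
  shift <- 2^(st$continental_group == "AFR")
  mu <- outer(rep(100, 30), shift)
  counts <- matrix(rnbinom(length(mu), size = 10, mu = mu), nrow = 30)
  # mostly-null transcriptome so size factors are estimable
  null_counts <- matrix(rnbinom(470 * n, size = 10, mu = 100), nrow = 470)
  all_counts <- rbind(counts, null_counts)
  rownames(all_counts) <- sprintf("g%03d", seq_len(nrow(all_counts)))
  ph <- phenotype_matrix(
    tibble::tibble(feature_id = rownames(all_counts),
                   gene_id = rownames(all_counts),
                   chrom = "chr1", tss = seq_len(nrow(all_counts)) * 1000L),
    all_counts, "counts")
  de <- nb_de(ph, st, "AFR")
  expect_gte(mean(de$q_value[1:30] <= 0.05), 0.9)
  expect_lt(mean(de$p[31:500] <= 0.05), 0.15)
  # deciles partition into equal-size bins
  expect_true(all(abs(table(de$decile) - 50) <= 1))
})

test_that("the NB test approaches the Poisson test for Poisson data", {
  st <- cohort(n_groups = 2, pops_per_group = 1, m = 50)
  n <- nrow(st)
  set.seed(4)
  counts <- matrix(rpois(150 * n, 80), nrow = 150)
  rownames(counts) <- sprintf("g%03d", 1:150)
  ph <- phenotype_matrix(
    tibble::tibble(feature_id = rownames(counts), gene_id = rownames(counts),
                   chrom = "chr1", tss = 1:150 * 1000L),
    counts, "counts")
  sf <- rep(1, n)
  de <- nb_de(ph, st, "AFR", size_factors = sf)
  focal <- as.numeric(st$continental_group == "AFR")
  p_pois <- apply(counts, 1, function(y) {
    f1 <- glm(y ~ focal, family = poisson())
    f0 <- glm(y ~ 1, family = poisson())
    pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE)
  })
  expect_lt(max(abs(sort(de$p) - sort(p_pois))), 0.05)
})

test_that("F_ST by DE decile is flat under the null and joins correctly", {
  leads <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                          variant_id = sprintf("v%02d", 1:40),
                          focal_group = "AFR", fst = 0.1)
  de <- tibble::tibble(gene_id = sprintf("g%02d", 1:40), focal_group = "AFR",
                       p = runif(40), q_value = runif(40, 0.2, 1))
  de$de <- de$q_value <= 0.05
  r <- rank(de$p, ties.method = "first")
  de$decile <- 11L - as.integer(ceiling(10 * r / nrow(de)))
  res <- fst_by_de_decile(leads, de)
  expect_equal(unique(res$deciles$mean_fst), 0.1)
  expect_true(all(res$deciles$n == 4))
  expect_error(fst_by_de_decile(leads[1:5, ], de[1:5, ]), "at least 10")
})
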