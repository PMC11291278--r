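# Structured-population simulator: nested Balding-Nichols genotypes over
# populations nested in continental groups, aFC-generative expression
# counts, Dirichlet splicing ratios, and a machine-readable truth table.

#' Simulation configuration
#'
#' Defaults emulate a 1KGP-like design: 5 continental groups holding 26
#' populations (7 + 4 + 5 + 5 + 5) of 28 samples each, group-level
#' differentiation F = 0.10 and within-group population differentiation
#' F = 0.01.
#'
#' @param n_genes Number of genes (each with its own disjoint cis window).
#' @param seed Mandatory integer seed.
#' @param n_groups Number of continental groups (5 gives AFR/AMR/EAS/EUR/SAS
#'   labels).
#' @param populations_per_group Integer vector (recycled) of populations in
#'   each group.
#' @param samples_per_population Samples per population (>= 2).
#' @param f_group Balding-Nichols differentiation of groups from the
#'   ancestral frequency.
#' @param f_pop Differentiation of populations from their group frequency.
#' @param variants_per_cis_window Variants simulated per gene window.
#' @param causal_prob Probabilities of 0-3 causal cis-variants per gene.
#' @param log2_afc_range Range of |log2 aFC| for causal effects.
#' @param causal_maf_min Minimum realized pooled MAF for a causal variant;
#'   candidates below it are re-drawn.
#' @param noise_sd_log2 SD of log2-scale expression noise.
#' @param batch_effect_sd SD of per-gene batch (and sex) effects on log2
#'   scale.
#' @param n_batches Number of sequencing batches, stratified within
#'   populations.
#' @param interaction_fraction Fraction of genes given a true
#'   genotype-by-group interaction.
#' @param interaction_delta Magnitude of the interaction log2 slope shift.
#' @param group_noise_multipliers Per-group multipliers of `noise_sd_log2`
#'   (heteroskedastic noise when not all 1).
#' @param ld Induce linkage disequilibrium by copying haplotype template
#'   blocks (default FALSE: variants are unlinked).
#' @param ld_block_length Variants per template block.
#' @param ld_templates Distinct template haplotypes per population per
#'   block.
#' @param ld_mutation Per-allele flip probability when copying a template.
#' @param overdispersion NULL for Poisson counts; a positive NB dispersion
#'   (e.g. 0.1) switches to negative-binomial counts.
#' @param expression_model `"afc"` (default): diploid mean is the average
#'   of the two haplotypes' multiplicative contributions (the allelic
#'   fold-change generative model). `"log_additive"`: log2 mean is linear
#'   in dosage (strictly additive allelic effects, no phase
#'   non-additivity).
#' @param base_mean_range Range (counts) of per-gene baseline means,
#'   sampled log-uniformly.
#' @param library_size_range Range of per-sample library-size multipliers,
#'   sampled log-uniformly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50,
                       seed = NULL,
                       n_groups = 5,
                       populations_per_group = c(7, 4, 5, 5, 5),
                       samples_per_population = 28,
                       f_group = 0.10,
                       f_pop = 0.01,
                       variants_per_cis_window = 200,
                       causal_prob = c(0.30, 0.40, 0.20, 0.10),
                       log2_afc_range = c(0.25, 2),
                       causal_maf_min = 0.05,
                       noise_sd_log2 = 0.5,
                       batch_effect_sd = 0.2,
                       n_batches = 4,
                       interaction_fraction = 0,
                       interaction_delta = 0.5,
                       group_noise_multipliers = rep(1, n_groups),
                       ld = FALSE,
                       ld_block_length = 20,
                       ld_templates = 6,
                       ld_mutation = 0.02,
                       overdispersion = NULL,
                       expression_model = c("afc", "log_additive"),
                       base_mean_range = c(32, 512),
                       library_size_range = c(0.5, 2)) {
  if (is.null(seed)) abort("sim_config requires an explicit seed")
  stopifnot(samples_per_population >= 2,
            f_group >= 0, f_group <= 1, f_pop >= 0, f_pop <= 1,
            interaction_fraction >= 0, interaction_fraction <= 1,
            abs(sum(causal_prob) - 1) < 1e-8)
  expression_model <- match.arg(expression_model)
  populations_per_group <- rep_len(populations_per_group, n_groups)
  group_noise_multipliers <- rep_len(group_noise_multipliers, n_groups)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

group_labels <- function(n_groups) {
  if (n_groups == 5) c("AFR", "AMR", "EAS", "EUR", "SAS")
  else sprintf("G%02d", seq_len(n_groups))
}

#' Build the simulated cohort's sample table
#'
#' @param config A [sim_config()].
#' @return A sample table with populations nested in groups, random sex,
#'   and batches stratified round-robin within each population.
#' @export
simulate_samples <- function(config) {
  groups <- group_labels(config$n_groups)
  pops <- unlist(lapply(seq_along(groups), function(i) {
    sprintf("%s_p%d", groups[i], seq_len(config$populations_per_group[i]))
  }))
  pop_group <- rep(groups, config$populations_per_group)
  m <- config$samples_per_population
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(length(pops) * m)),
    population = rep(pops, each = m),
    continental_group = rep(pop_group, each = m),
    sex = sample(c("F", "M"), length(pops) * m, replace = TRUE),
    batch = rep_len(seq_len(config$n_batches), length(pops) * m)
  )
}

# Nested Balding-Nichols draw: child AF ~ Beta(p(1-F)/F, (1-p)(1-F)/F);
# F = 0 degenerates to the parent frequency exactly.
bn_draw <- function(p, f) {
  if (f == 0) return(p)
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate structured-population genotypes
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); group and
#' population frequencies follow nested Balding-Nichols draws controlled
#' by `f_group` and `f_pop`. Haplotypes are Bernoulli draws from the
#' population frequency, optionally copied from per-population template
#' haplotypes in blocks to induce linkage disequilibrium.
#'
#' @param config A [sim_config()].
#' @param samples Optional pre-built sample table (defaults to
#'   [simulate_samples()]).
#' @param seed Optional seed override; `config$seed` is used when the
#'   function is called standalone, `NA` suppresses re-seeding (for use
#'   inside [simulate_study()]).
#' @return A phased [genotype_matrix()] with attributes `af` (per-variant
#'   ancestral/group/population frequencies), `gene_map` (gene windows)
#'   and `samples`.
#' @export
simulate_genotypes <- function(config, samples = NULL, seed = config$seed) {
  if (!is.na(seed)) set.seed(seed)
  if (is.null(samples)) samples <- simulate_samples(config)
  samples <- as_sample_table(samples)
  groups <- group_labels(config$n_groups)
  pops <- unique(samples$population)
  pop_group <- samples$continental_group[match(pops, samples$population)]
  n <- nrow(samples)
  m_per_gene <- config$variants_per_cis_window
  p_total <- config$n_genes * m_per_gene

  window <- 1e6
  spacing <- 2 * window + 5e5
  # disjoint cis windows; 800 genes per chromosome keeps positions within
  # 32-bit integer range
  per_chrom <- 800L
  chrom_idx <- (seq_len(config$n_genes) - 1L) %/% per_chrom + 1L
  within <- (seq_len(config$n_genes) - 1L) %% per_chrom
  tss <- as.integer(window + 2.5e5 + within * spacing)
  chroms <- sprintf("chr%d", chrom_idx)
  pos <- unlist(lapply(tss, function(t0) {
    sort(sample.int(2L * as.integer(window) + 1L, m_per_gene) + t0 - as.integer(window) - 1L)
  }))
  stopifnot(!anyNA(pos))
  gene_id <- rep(sprintf("g%04d", seq_len(config$n_genes)), each = m_per_gene)
  chrom_v <- rep(chroms, each = m_per_gene)
  variant_id <- sprintf("%s_%d_A_G", chrom_v, pos)

  p_anc <- runif(p_total, 0.05, 0.95)
  af_group <- sapply(groups, function(g) bn_draw(p_anc, config$f_group))
  af_pop <- sapply(seq_along(pops), function(i) {
    bn_draw(af_group[, pop_group[i]], config$f_pop)
  })
  colnames(af_pop) <- pops

  h1 <- matrix(0L, p_total, n)
  h2 <- matrix(0L, p_total, n)
  for (i in seq_along(pops)) {
    idx <- which(samples$population == pops[i])
    afp <- af_pop[, i]
    if (!config$ld) {
      h1[, idx] <- rbinom(p_total * length(idx), 1L, afp)
      h2[, idx] <- rbinom(p_total * length(idx), 1L, afp)
    } else {
      for (gi in seq_len(config$n_genes)) {
        rows <- ((gi - 1) * m_per_gene + 1):(gi * m_per_gene)
        starts <- seq(1, m_per_gene, by = config$ld_block_length)
        for (s in starts) {
          blk <- rows[s:min(s + config$ld_block_length - 1, m_per_gene)]
          tmpl <- matrix(rbinom(length(blk) * config$ld_templates, 1L, afp[blk]),
                         nrow = length(blk))
          pick1 <- sample.int(config$ld_templates, length(idx), replace = TRUE)
          pick2 <- sample.int(config$ld_templates, length(idx), replace = TRUE)
          b1 <- tmpl[, pick1, drop = FALSE]
          b2 <- tmpl[, pick2, drop = FALSE]
          flip1 <- matrix(rbinom(length(b1), 1L, config$ld_mutation), nrow = nrow(b1))
          flip2 <- matrix(rbinom(length(b2), 1L, config$ld_mutation), nrow = nrow(b2))
          h1[blk, idx] <- (b1 + flip1) %% 2L
          h2[blk, idx] <- (b2 + flip2) %% 2L
        }
      }
    }
  }
  colnames(h1) <- colnames(h2) <- samples$sample_id
  variants <- tibble::tibble(chrom = chrom_v, pos = pos, ref = "A", alt = "G",
                             variant_id = variant_id)
  g <- genotype_matrix(variants, h1 + h2, list(hap1 = h1, hap2 = h2))
  attr(g, "af") <- tibble::tibble(
    variant_id = variant_id, gene_id = gene_id, ancestral_p = p_anc,
    tibble::as_tibble(af_group), tibble::as_tibble(af_pop)
  )
  attr(g, "gene_map") <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(config$n_genes)),
    chrom = chroms, tss = tss,
    first_variant = (seq_len(config$n_genes) - 1) * m_per_gene + 1L,
    last_variant = seq_len(config$n_genes) * m_per_gene
  )
  attr(g, "samples") <- samples
  g
}

draw_causal_truth <- function(genotypes, config) {
  gene_map <- attr(genotypes, "gene_map")
  samples <- attr(genotypes, "samples")
  dos <- genotypes$dosages
  pooled_maf <- pmin(rowMeans(dos) / 2, 1 - rowMeans(dos) / 2)
  groups <- unique(samples$continental_group)
  genes <- list(); causal <- list()
  for (i in seq_len(nrow(gene_map))) {
    rows <- gene_map$first_variant[i]:gene_map$last_variant[i]
    eligible <- rows[pooled_maf[rows] >= config$causal_maf_min]
    n_causal <- sample(0:3, 1, prob = config$causal_prob)
    n_causal <- min(n_causal, length(eligible))
    cv <- if (n_causal > 0) sample(eligible, n_causal) else integer(0)
    beta <- runif(n_causal, config$log2_afc_range[1], config$log2_afc_range[2]) *
      sample(c(-1, 1), n_causal, replace = TRUE)
    has_inter <- n_causal > 0 && runif(1) < config$interaction_fraction
    inter_variant <- if (has_inter) cv[1] else NA_integer_
    inter_group <- if (has_inter) sample(groups, 1) else NA_character_
    inter_delta <- if (has_inter) config$interaction_delta * sample(c(-1, 1), 1) else 0
    genes[[i]] <- tibble::tibble(
      gene_id = gene_map$gene_id[i], n_causal = n_causal,
      interaction_variant = if (has_inter) genotypes$variants$variant_id[inter_variant] else NA_character_,
      interaction_group = inter_group, interaction_delta = inter_delta
    )
    if (n_causal > 0) {
      causal[[length(causal) + 1]] <- tibble::tibble(
        gene_id = gene_map$gene_id[i],
        variant_id = genotypes$variants$variant_id[cv],
        variant_row = cv, log2_afc = beta
      )
    }
  }
  list(genes = dplyr::bind_rows(genes),
       causal = if (length(causal)) dplyr::bind_rows(causal)
                else tibble::tibble(gene_id = character(), variant_id = character(),
                                    variant_row = integer(), log2_afc = double()))
}

#' Simulate expression counts under the allelic-fold-change model
#'
#' Each haplotype contributes \eqn{\prod_k 2^{\beta_k a_k}} over the causal
#' variants it carries; the individual mean is the haplotype average times
#' a per-gene baseline, batch/sex/interaction factors and log-normal
#' noise; counts are Poisson (or negative binomial) around the mean scaled
#' by a per-sample library size.
#'
#' @param genotypes Phased [genotype_matrix()] from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param truth Optional pre-drawn truth (as returned in the `truth`
#'   attribute); drawn fresh when NULL.
#' @param seed Seed override (see [simulate_genotypes()]).
#' @return A counts [phenotype_matrix()] with attributes `truth` (gene and
#'   causal-variant tables, batch/sex effects, library sizes) and
#'   `library_sizes`.
#' @export
simulate_expression <- function(genotypes, config, truth = NULL,
                                seed = config$seed) {
  if (!is.na(seed)) set.seed(seed + 1L)
  samples <- attr(genotypes, "samples")
  gene_map <- attr(genotypes, "gene_map")
  if (is.null(truth)) truth <- draw_causal_truth(genotypes, config)
  n <- nrow(samples)
  G <- config$n_groups
  groups <- group_labels(G)
  grp_idx <- match(samples$continental_group, groups)
  lib <- exp(runif(n, log(config$library_size_range[1]),
                   log(config$library_size_range[2])))
  base_mean <- exp(runif(nrow(gene_map), log(config$base_mean_range[1]),
                         log(config$base_mean_range[2])))
  batch_eff <- matrix(rnorm(nrow(gene_map) * config$n_batches, 0,
                            config$batch_effect_sd), nrow(gene_map))
  sex_eff <- rnorm(nrow(gene_map), 0, config$batch_effect_sd)
  noise_sd <- config$noise_sd_log2 * config$group_noise_multipliers[grp_idx]

  h1 <- genotypes$haplotypes$hap1
  h2 <- genotypes$haplotypes$hap2
  counts <- matrix(0, nrow(gene_map), n,
                   dimnames = list(gene_map$gene_id, samples$sample_id))
  for (i in seq_len(nrow(gene_map))) {
    cz <- truth$causal[truth$causal$gene_id == gene_map$gene_id[i], ]
    l2h1 <- l2h2 <- rep(0, n)
    if (nrow(cz) > 0) {
      for (k in seq_len(nrow(cz))) {
        l2h1 <- l2h1 + cz$log2_afc[k] * h1[cz$variant_row[k], ]
        l2h2 <- l2h2 + cz$log2_afc[k] * h2[cz$variant_row[k], ]
      }
    }
    genetic <- if (config$expression_model == "log_additive") {
      2^(l2h1 + l2h2)
    } else {
      (2^l2h1 + 2^l2h2) / 2
    }
    tg <- truth$genes[i, ]
    inter <- 0
    if (!is.na(tg$interaction_variant)) {
      gv <- genotypes$dosages[match(tg$interaction_variant,
                                    genotypes$variants$variant_id), ]
      inter <- tg$interaction_delta * gv *
        (samples$continental_group == tg$interaction_group)
    }
    mu <- base_mean[i] * genetic *
      2^(batch_eff[i, samples$batch] + sex_eff[i] * (samples$sex == "M") +
           inter + rnorm(n, 0, noise_sd))
    lambda <- lib * mu
    counts[i, ] <- if (is.null(config$overdispersion)) {
      rpois(n, lambda)
    } else {
      rnbinom_mu(n, mu = lambda, dispersion = config$overdispersion)
    }
  }
  features <- tibble::tibble(
    feature_id = gene_map$gene_id, gene_id = gene_map$gene_id,
    chrom = gene_map$chrom, tss = gene_map$tss, strand = "+",
    cluster_id = NA_character_
  )
  out <- phenotype_matrix(features, counts, "counts")
  truth$genes$base_mean <- base_mean
  attr(out, "truth") <- truth
  attr(out, "library_sizes") <- setNames(lib, samples$sample_id)
  out
}

rnbinom_mu <- function(n, mu, dispersion) {
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate intron-excision splicing ratios
#'
#' Each gene carries one splicing cluster of 2-4 introns with Dirichlet
#' usage; a gene with an sQTL has one intron whose Dirichlet concentration
#' is shifted multiplicatively by \eqn{2^{\beta g}}. Ratios sum to 1
#' within each cluster for every sample.
#'
#' @param genotypes Phased [genotype_matrix()].
#' @param config A [sim_config()]; `P(sQTL) = 1 - causal_prob[1]`.
#' @param seed Seed override (see [simulate_genotypes()]).
#' @return A ratios [phenotype_matrix()] (features are introns, ids
#'   `gene:cluster:intron`) with a `truth` attribute.
#' @export
simulate_splicing <- function(genotypes, config, seed = config$seed) {
  if (!is.na(seed)) set.seed(seed + 2L)
  samples <- attr(genotypes, "samples")
  gene_map <- attr(genotypes, "gene_map")
  dos <- genotypes$dosages
  pooled_maf <- pmin(rowMeans(dos) / 2, 1 - rowMeans(dos) / 2)
  n <- nrow(samples)
  feats <- list(); vals <- list(); truth <- list()
  for (i in seq_len(nrow(gene_map))) {
    k <- sample(2:4, 1)
    alpha0 <- runif(k, 2, 10)
    rows <- gene_map$first_variant[i]:gene_map$last_variant[i]
    eligible <- rows[pooled_maf[rows] >= config$causal_maf_min]
    has_qtl <- length(eligible) > 0 && runif(1) < (1 - config$causal_prob[1])
    sv <- if (has_qtl) sample(eligible, 1) else NA_integer_
    beta <- if (has_qtl) {
      runif(1, config$log2_afc_range[1], config$log2_afc_range[2]) * sample(c(-1, 1), 1)
    } else 0
    target <- sample.int(k, 1)
    A <- matrix(alpha0, k, n)
    if (has_qtl) A[target, ] <- A[target, ] * 2^(beta * dos[sv, ])
    draws <- matrix(rgamma(k * n, shape = A), k, n)
    ratios <- sweep(draws, 2, colSums(draws), "/")
    cl <- sprintf("clu%04d", i)
    ids <- sprintf("%s:%s:i%d", gene_map$gene_id[i], cl, seq_len(k))
    feats[[i]] <- tibble::tibble(
      feature_id = ids, gene_id = gene_map$gene_id[i],
      chrom = gene_map$chrom[i], tss = gene_map$tss[i], strand = "+",
      cluster_id = cl
    )
    vals[[i]] <- ratios
    truth[[i]] <- tibble::tibble(
      gene_id = gene_map$gene_id[i], cluster_id = cl,
      sqtl_variant = if (has_qtl) genotypes$variants$variant_id[sv] else NA_character_,
      log2_shift = beta, target_intron = ids[target]
    )
  }
  features <- dplyr::bind_rows(feats)
  values <- do.call(rbind, vals)
  colnames(values) <- samples$sample_id
  out <- phenotype_matrix(features, values, "ratios")
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Simulate phenotypes with fixed between-group/population variance
#'
#' Companion generator for variance-partitioning calibration: values are
#' group effect + population effect + unit Gaussian noise, with effect SDs
#' chosen so the expected between-group and between-population variance
#' fractions equal the targets. Used for the variance-partitioning
#' recovery and permutation-calibration checks.
#'
#' @param samples A sample table.
#' @param n_features Number of features to draw.
#' @param var_frac_group Target fraction of variance between continental
#'   groups (0-1).
#' @param var_frac_population Target fraction between populations (>=
#'   `var_frac_group`; population labels refine group labels).
#' @param group_noise_multipliers Optional per-group noise SD multipliers.
#' @param seed Integer seed.
#' @return A "normalized" [phenotype_matrix()] with a `truth` attribute
#'   giving the target fractions.
#' @export
simulate_structured_phenotypes <- function(samples, n_features,
                                           var_frac_group = 0,
                                           var_frac_population = 0,
                                           group_noise_multipliers = NULL,
                                           seed = 1) {
  stopifnot(var_frac_population >= var_frac_group,
            var_frac_population < 1)
  set.seed(seed)
  samples <- as_sample_table(samples)
  n <- nrow(samples)
  groups <- unique(samples$continental_group)
  pops <- unique(samples$population)
  # unit within-population noise; group/population effects are drawn, then
  # rescaled per feature so the realized between-population variance
  # fraction (relative to unit noise) equals the target exactly
  v_tot_eff <- var_frac_population / (1 - var_frac_population)
  v_g <- v_tot_eff * if (var_frac_population > 0) var_frac_group / var_frac_population else 0
  v_p <- v_tot_eff - v_g
  noise_sd <- rep(1, n)
  if (!is.null(group_noise_multipliers)) {
    noise_sd <- group_noise_multipliers[match(samples$continental_group, groups)]
  }
  vals <- matrix(0, n_features, n,
                 dimnames = list(sprintf("f%04d", seq_len(n_features)),
                                 samples$sample_id))
  realized_group <- numeric(n_features)
  for (i in seq_len(n_features)) {
    eff <- rnorm(length(groups), 0, sqrt(v_g))[match(samples$continental_group, groups)] +
      rnorm(length(pops), 0, sqrt(v_p))[match(samples$population, pops)]
    eff <- eff - mean(eff)
    if (var_frac_population > 0 && mean(eff^2) > 0) {
      eff <- eff * sqrt(v_tot_eff / mean(eff^2))
    }
    gmeans <- ave(eff, samples$continental_group)
    realized_group[i] <- mean(gmeans^2) / (v_tot_eff + 1)
    vals[i, ] <- eff + rnorm(n, 0, noise_sd)
  }
  features <- tibble::tibble(
    feature_id = rownames(vals), gene_id = rownames(vals), chrom = "chr1",
    tss = seq_len(n_features) * 1000L, strand = "+", cluster_id = NA_character_
  )
  out <- phenotype_matrix(features, vals, "normalized")
  attr(out, "truth") <- tibble::tibble(
    feature_id = rownames(vals),
    var_frac_group = realized_group,
    var_frac_population = var_frac_population
  )
  out
}

#' Simulate a complete synthetic study
#'
#' Genotypes, expression counts, optional splicing ratios, sample table
#' and ground truth, all driven by one seed.
#'
#' @param config A [sim_config()].
#' @param splicing Also simulate splicing ratios (default TRUE).
#' @return A list with elements `genotypes`, `expression`, `splicing`
#'   (or NULL), `samples`, `truth` (list: `genes`, `causal`, `splicing`,
#'   `af`), and `config`.
#' @export
simulate_study <- function(config, splicing = TRUE) {
  set.seed(config$seed)
  samples <- simulate_samples(config)
  geno <- simulate_genotypes(config, samples = samples, seed = NA)
  expr <- simulate_expression(geno, config, seed = config$seed)
  spl <- if (splicing) simulate_splicing(geno, config, seed = config$seed) else NULL
  truth <- attr(expr, "truth")
  list(genotypes = geno, expression = expr, splicing = spl,
       samples = samples,
       truth = list(genes = truth$genes, causal = truth$causal,
                    splicing = if (splicing) attr(spl, "truth") else NULL,
                    af = attr(geno, "af")),
       config = config)
}

#' Write a simulated study to disk
#'
#' Emits the VCF, phenotype BED(s), sample TSV and truth-table TSVs that
#' the readers in this package consume unchanged.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_phenotype_bed(sim$expression, file.path(dir, "expression.bed"))
  if (!is.null(sim$splicing)) {
    write_phenotype_bed(sim$splicing, file.path(dir, "splicing.bed"))
  }
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$causal, file.path(dir, "truth_causal.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$af, file.path(dir, "truth_af.tsv"), progress = FALSE)
  invisible(dir)
}
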