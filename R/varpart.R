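# Variance partitioning of (residualized) phenotypes between continental
# groups and populations, with a joint-label permutation null and a
# between-group variance (heteroskedasticity) deviance test.

eta_squared <- function(vals, labels) {
  # rows = features; returns per-feature SSB/SST and the omega-squared
  # style bias-adjusted fraction (SSB - (k-1) MSW) / (SST + MSW)
  labels <- as.factor(labels)
  n <- ncol(vals)
  k <- nlevels(labels)
  cnt <- as.vector(table(labels))
  tot <- rowSums(vals)
  grand <- tot / n
  gm <- t(rowsum(t(vals), labels)) / rep(cnt, each = nrow(vals))
  ssb <- rowSums(sweep(gm, 1, grand, "-")^2 * rep(cnt, each = nrow(vals)))
  sst <- rowSums(vals^2) - n * grand^2
  eta2 <- ifelse(sst > 0, ssb / sst, 0)
  msw <- (sst - ssb) / (n - k)
  adj <- ifelse(sst + msw > 0, (ssb - (k - 1) * msw) / (sst + msw), 0)
  list(eta2 = eta2, adj = pmax(adj, -1))
}

#' Partition phenotype variance between groups and populations
#'
#' Per-feature eta-squared from two separate one-way fits: one on
#' continental-group labels, one on population labels. Because population
#' labels refine group labels, the population fraction is at least the
#' group fraction for every feature. `pct_var_*_adj` are the
#' omega-squared style bias-adjusted fractions (the naive eta-squared of a
#' null feature has expectation about `(k-1)/(n-1)`).
#'
#' @param values Residualized phenotype values: a [phenotype_matrix()] or
#'   a features x samples matrix.
#' @param samples Sample table aligned with the value columns.
#' @return A tibble with one row per feature: `pct_var_group`,
#'   `pct_var_population` and their `_adj` versions, all in percent. A
#'   `summary` attribute holds across-feature means and SDs.
#' @export
partition_variance <- function(values, samples) {
  vals <- if (inherits(values, "phenotype_matrix")) values$values else as.matrix(values)
  samples <- as_sample_table(samples)
  stopifnot(ncol(vals) == nrow(samples))
  if (any(table(samples$population) < 2)) abort("every population needs >= 2 samples")
  eg <- eta_squared(vals, samples$continental_group)
  ep <- eta_squared(vals, samples$population)
  out <- tibble::tibble(
    feature_id = rownames(vals) %||% sprintf("f%d", seq_len(nrow(vals))),
    pct_var_group = 100 * eg$eta2,
    pct_var_population = 100 * ep$eta2,
    pct_var_group_adj = 100 * eg$adj,
    pct_var_population_adj = 100 * ep$adj
  )
  attr(out, "summary") <- tibble::tibble(
    level = c("continental_group", "population"),
    mean_pct = c(mean(out$pct_var_group), mean(out$pct_var_population)),
    sd_pct = c(sd(out$pct_var_group), sd(out$pct_var_population)),
    mean_pct_adj = c(mean(out$pct_var_group_adj), mean(out$pct_var_population_adj))
  )
  out
}

#' Permutation null for the variance-partition statistic
#'
#' The global statistic is the across-feature mean eta-squared, computed
#' for both label levels. Population and group labels are permuted
#' jointly (sample indices shuffled), preserving the nesting. One-tailed
#' p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param values Residualized values (matrix or [phenotype_matrix()]).
#' @param samples Sample table.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return A tibble with one row per label level: observed mean
#'   eta-squared (percent) and permutation p-value.
#' @export
permutation_null <- function(values, samples, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 100)
  vals <- if (inherits(values, "phenotype_matrix")) values$values else as.matrix(values)
  samples <- as_sample_table(samples)
  set.seed(seed)
  obs_g <- mean(eta_squared(vals, samples$continental_group)$eta2)
  obs_p <- mean(eta_squared(vals, samples$population)$eta2)
  n <- ncol(vals)
  null_g <- null_p <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    null_g[b] <- mean(eta_squared(vals, samples$continental_group[idx])$eta2)
    null_p[b] <- mean(eta_squared(vals, samples$population[idx])$eta2)
  }
  tibble::tibble(
    level = c("continental_group", "population"),
    observed_mean_pct = 100 * c(obs_g, obs_p),
    p_value = c((1 + sum(null_g >= obs_g)) / (1 + n_perm),
                (1 + sum(null_p >= obs_p)) / (1 + n_perm)),
    n_perm = n_perm
  )
}

#' Between-group variance (heteroskedasticity) test
#'
#' Per-feature per-group sample variances (N = features x groups
#' observations) are modelled with a Gamma GLM with log link on the group
#' label; an analysis-of-deviance likelihood-ratio chi-squared against the
#' intercept-only model (df = n_groups - 1) gives a one-tailed p-value.
#' Zero variance cells are floored at 1e-12 and flagged.
#'
#' @param values Residualized values (matrix or [phenotype_matrix()]).
#' @param samples Sample table.
#' @return A list: `variances` tibble (feature, group, variance),
#'   `group_means` tibble of mean within-group variance per group,
#'   `statistic` (chi-squared), `df`, `p_value`, `n_obs`, `n_floored`.
#' @export
group_variance_test <- function(values, samples) {
  vals <- if (inherits(values, "phenotype_matrix")) values$values else as.matrix(values)
  samples <- as_sample_table(samples)
  groups <- unique(samples$continental_group)
  if (any(table(samples$continental_group) < 2)) abort("every group needs >= 2 samples")
  per_group <- lapply(groups, function(g) {
    idx <- samples$continental_group == g
    apply(vals[, idx, drop = FALSE], 1, var)
  })
  v <- unlist(per_group)
  n_floored <- sum(v <= 0)
  if (n_floored > 0) {
    warn(sprintf("flooring %d zero-variance cell(s)", n_floored))
    v[v <= 0] <- 1e-12
  }
  glab <- factor(rep(groups, each = nrow(vals)))
  fit1 <- glm(v ~ glab, family = Gamma(link = "log"))
  fit0 <- glm(v ~ 1, family = Gamma(link = "log"))
  phi <- summary(fit1)$dispersion
  stat <- (fit0$deviance - fit1$deviance) / phi
  df <- length(groups) - 1L
  p <- pchisq(stat, df, lower.tail = FALSE)
  list(
    variances = tibble::tibble(
      feature_id = rep(rownames(vals) %||% sprintf("f%d", seq_len(nrow(vals))),
                       times = length(groups)),
      group = rep(groups, each = nrow(vals)),
      variance = unlist(per_group)
    ),
    group_means = tibble::tibble(
      group = groups,
      mean_variance = vapply(per_group, mean, numeric(1))
    ),
    statistic = stat, df = df, p_value = p,
    n_obs = length(v), n_floored = n_floored
  )
}
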