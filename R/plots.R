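# ggplot2 views of the main result types.

#' Plot variance partition fractions
#'
#' Violin/jitter view of per-feature percent variance explained by
#' continental-group and population labels.
#'
#' @param varpart Result of [partition_variance()].
#' @return A ggplot object.
#' @export
plot_varpart <- function(varpart) {
  long <- tidyr::pivot_longer(
    varpart[, c("feature_id", "pct_var_group", "pct_var_population")],
    cols = c("pct_var_group", "pct_var_population"),
    names_to = "level", values_to = "pct")
  long$level <- ifelse(long$level == "pct_var_group",
                       "continental group", "population")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$pct)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = NULL, y = "% variance explained") +
    ggplot2::theme_minimal()
}

#' Plot a fine-mapping fit
#'
#' Per-variant posterior inclusion probabilities along the cis window,
#' coloured by credible-set membership.
#'
#' @param object A [susie_fit()].
#' @param sets Optional credible sets from [extract_credible_sets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot susie_fit
#' @export
autoplot.susie_fit <- function(object, sets = NULL, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  d$set <- "none"
  if (!is.null(sets) && nrow(sets) > 0) {
    for (i in seq_len(nrow(sets))) {
      d$set[d$variant_id %in% sets$variants[[i]]$variant_id] <- sets$set_id[i]
    }
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$pip,
                                  colour = .data$set)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "variant (position order)", y = "PIP",
                  colour = "credible set") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot mean lead F_ST by differential-expression decile
#'
#' @param decile_result Result of [fst_by_de_decile()].
#' @return A ggplot object.
#' @export
plot_fst_deciles <- function(decile_result) {
  ggplot2::ggplot(decile_result$deciles,
                  ggplot2::aes(x = factor(.data$decile), y = .data$mean_fst)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "differential-expression decile (10 = most significant)",
                  y = expression("mean lead-eQTL" ~ F[ST])) +
    ggplot2::theme_minimal()
}

#' Plot enrichment estimates with confidence intervals
#'
#' @param enrichment Tibble from [enrichment_scan()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$log2_fold, y = .data$annotation)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(log[2] ~ "fold enrichment"), y = NULL) +
    ggplot2::theme_minimal()
}
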