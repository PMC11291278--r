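# Enrichment of lead QTLs in genomic annotations against background
# variants matched on MAF and TSS distance (10 x 10 decile bins),
# with percentile-bootstrap confidence intervals.

#' Annotation membership for variants
#'
#' Interval annotations use 0-based half-open BED coordinates: a variant
#' at 1-based position `pos` is inside an interval iff
#' `start <= pos - 1 < end`. Membership is resolved per chromosome with
#' a sorted-start binary search over a running maximum of interval ends.
#' Label annotations match `variant_id` against a label table; a variant
#' may belong to several annotations.
#'
#' @param variants Tibble with `chrom`, `pos`, `variant_id`.
#' @param annotation Either a tibble of intervals (`chrom`, `start`,
#'   `end`) or of labels (`variant_id`, `label`) together with a `label`
#'   value to test via the `label` argument.
#' @param label When `annotation` is a label table, the category to test.
#' @return Logical vector along `variants`.
#' @export
annotate_variants <- function(variants, annotation, label = NULL) {
  if (!is.null(label) || "label" %in% names(annotation)) {
    stopifnot(!is.null(label))
    hits <- annotation$variant_id[annotation$label == label]
    return(variants$variant_id %in% hits)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(annotation)))
  if (any(annotation$end <= annotation$start)) abort("malformed interval (end <= start)")
  out <- rep(FALSE, nrow(variants))
  for (ch in unique(variants$chrom)) {
    iv <- annotation[annotation$chrom == ch, , drop = FALSE]
    vi <- which(variants$chrom == ch)
    if (nrow(iv) == 0 || length(vi) == 0) next
    o <- order(iv$start)
    starts <- iv$start[o]
    maxend <- cummax(iv$end[o])
    pos0 <- variants$pos[vi] - 1L
    idx <- findInterval(pos0, starts)   # last interval with start <= pos0
    inside <- idx >= 1 & pos0 < ifelse(idx >= 1, maxend[pmax(idx, 1)], 0)
    out[vi] <- inside
  }
  out
}

#' Draw MAF- and TSS-distance-matched background variants
#'
#' The candidate pool (all cis-tested variants minus the leads) is binned
#' by pool-MAF decile x pool-|TSS distance| decile. Each draw samples,
#' for every lead, one pool variant uniformly from the lead's joint bin,
#' without replacement within the draw. Empty or exhausted bins widen to
#' the nearest non-empty neighbouring bins (expanding ring in the 10 x 10
#' grid), with a warning.
#'
#' @param leads Tibble with `variant_id`, `maf`, `tss_distance`.
#' @param pool Tibble with the same columns (leads excluded).
#' @param n_draws Number of background draws (default 1000).
#' @param seed Integer seed.
#' @return Integer matrix `n_draws` x `nrow(leads)` of pool row indices;
#'   bin breaks attached as attributes.
#' @export
matched_background <- function(leads, pool, n_draws = 1000, seed = 1) {
  stopifnot(nrow(pool) >= nrow(leads))
  set.seed(seed)
  qmaf <- unique(quantile(pool$maf, probs = seq(0, 1, 0.1), names = FALSE))
  qdist <- unique(quantile(abs(pool$tss_distance), probs = seq(0, 1, 0.1),
                           names = FALSE))
  bin_of <- function(x, br) pmin(pmax(findInterval(x, br, all.inside = TRUE), 1),
                                 length(br) - 1)
  pool_bm <- bin_of(pool$maf, qmaf)
  pool_bd <- bin_of(abs(pool$tss_distance), qdist)
  lead_bm <- bin_of(leads$maf, qmaf)
  lead_bd <- bin_of(abs(leads$tss_distance), qdist)
  nbm <- length(qmaf) - 1; nbd <- length(qdist) - 1
  pool_bin <- (pool_bm - 1) * nbd + pool_bd
  bin_members <- split(seq_len(nrow(pool)), factor(pool_bin, levels = seq_len(nbm * nbd)))
  widened <- FALSE
  candidates_for <- function(bm, bd, need) {
    ring <- 0
    repeat {
      bms <- max(1, bm - ring):min(nbm, bm + ring)
      bds <- max(1, bd - ring):min(nbd, bd + ring)
      cand <- unlist(bin_members[as.vector(outer((bms - 1) * nbd, bds, "+"))],
                     use.names = FALSE)
      if (length(cand) >= need) return(cand)
      if (ring > 0) widened <<- TRUE
      ring <- ring + 1
      if (ring > max(nbm, nbd)) return(seq_len(nrow(pool)))
    }
  }
  draws <- matrix(0L, n_draws, nrow(leads))
  for (d in seq_len(n_draws)) {
    used <- logical(nrow(pool))
    for (i in seq_len(nrow(leads))) {
      cand <- candidates_for(lead_bm[i], lead_bd[i], 1L)
      cand <- cand[!used[cand]]
      if (length(cand) == 0) {
        cand <- candidates_for(lead_bm[i], lead_bd[i], nrow(leads))
        cand <- cand[!used[cand]]
      }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      draws[d, i] <- pick
      used[pick] <- TRUE
    }
  }
  if (widened) warn("some matching bins were widened to neighbouring bins")
  attr(draws, "maf_breaks") <- qmaf
  attr(draws, "dist_breaks") <- qdist
  draws
}

#' Enrichment with percentile-bootstrap confidence interval
#'
#' Fold enrichment = (proportion of leads in the annotation) / (mean
#' background proportion across draws), reported as log2 fold with a 95%
#' percentile CI over per-draw log2 ratios. Draws (or lead sets) with a
#' zero proportion use a pseudo-count of `0.5 / n_leads`. Categories with
#' fewer than `min_leads` annotated leads are refused.
#'
#' @param lead_in Logical vector: lead membership in the annotation.
#' @param draw_in Logical matrix `n_draws` x `n_leads`: background
#'   membership per draw (e.g. `matrix(ann[draws], nrow(draws))`).
#' @param min_leads Minimum annotated leads (default 5).
#' @return One-row tibble: `n_lead_in`, `n_lead_total`,
#'   `mean_background_prop`, `log2_fold`, `ci_low`, `ci_high`,
#'   `n_background_draws`.
#' @export
enrichment_ci <- function(lead_in, draw_in, min_leads = 5) {
  n <- length(lead_in)
  if (sum(lead_in) < min_leads) {
    abort(sprintf("fewer than %d lead variants in category", min_leads))
  }
  if (!any(draw_in)) abort("annotation absent from the background pool")
  pseudo <- 0.5 / n
  p_lead <- max(mean(lead_in), pseudo)
  p_draw <- pmax(rowMeans(draw_in), pseudo)
  l2 <- log2(p_lead / p_draw)
  ci <- quantile(l2, c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    n_lead_in = sum(lead_in), n_lead_total = n,
    mean_background_prop = mean(rowMeans(draw_in)),
    log2_fold = log2(p_lead / mean(p_draw)),
    ci_low = ci[1], ci_high = ci[2],
    n_background_draws = nrow(draw_in)
  )
}

#' Lead-QTL enrichment across annotations
#'
#' Runs [annotate_variants()], [matched_background()] and
#' [enrichment_ci()] for each annotation in a named list.
#'
#' @param leads Tibble with `variant_id`, `chrom`, `pos`, `maf`,
#'   `tss_distance`.
#' @param pool Tibble with the same columns (cis-tested variants minus
#'   leads).
#' @param annotations Named list of annotation tibbles (interval or
#'   label; label tables must carry a `label` column whose unique values
#'   are each tested).
#' @param n_draws,seed Passed to [matched_background()].
#' @param min_leads Category floor (default 5); failing categories are
#'   skipped with a message.
#' @return Tibble with one row per annotation.
#' @export
enrichment_scan <- function(leads, pool, annotations, n_draws = 1000,
                            seed = 1, min_leads = 5) {
  draws <- matched_background(leads, pool, n_draws = n_draws, seed = seed)
  out <- list()
  for (nm in names(annotations)) {
    ann <- annotations[[nm]]
    labels <- if ("label" %in% names(ann)) unique(ann$label) else NA
    for (lb in labels) {
      lead_in <- annotate_variants(leads, ann, label = if (is.na(lb)) NULL else lb)
      pool_in <- annotate_variants(pool, ann, label = if (is.na(lb)) NULL else lb)
      row <- tryCatch(
        enrichment_ci(lead_in, matrix(pool_in[draws], nrow(draws))),
        error = function(e) NULL)
      if (is.null(row)) {
        inform(sprintf("skipping %s%s: too few annotated leads", nm,
                       if (is.na(lb)) "" else paste0(":", lb)))
        next
      }
      row$annotation <- if (is.na(lb)) nm else paste0(nm, ":", lb)
      out[[length(out) + 1]] <- row
    }
  }
  dplyr::bind_rows(out)
}
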