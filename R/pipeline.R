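# End-to-end orchestration of the synthetic-study workflow: simulate ->
# prep -> variance partition -> scan -> fine-map -> aFC -> population
# differentiation -> interaction tests -> enrichment -> colocalization,
# with plain-TSV interchange and a JSON run manifest.

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  listcols <- vapply(x, is.list, logical(1))
  readr::write_tsv(x[, !listcols, drop = FALSE], path, progress = FALSE)
  path
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a study from `config`, writes the inputs to disk, reads
#' them back through the package's own readers, and runs every analysis
#' stage, leaving one TSV per stage plus a JSON manifest in `out_dir`.
#' Identical config and seed give bitwise-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param n_perm Permutations for the scan stage (default 200).
#' @param n_pcs Expression PCs in the covariate design (default 10).
#' @param fdr Gene-level FDR (default 0.05).
#' @param L Maximum fine-mapped effects per gene (default 5).
#' @param splicing Include the splicing arm (default TRUE).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_qtl_study <- function(config, out_dir, n_perm = 200, n_pcs = 10,
                          fdr = 0.05, L = 5, splicing = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   stages = list())
  t_last <- Sys.time()
  tick <- function(name, n_rows) {
    manifest$stages[[name]] <<- list(
      rows = n_rows,
      seconds = round(as.numeric(difftime(Sys.time(), t_last, units = "secs")), 2))
    t_last <<- Sys.time()
  }

  sim <- simulate_study(config, splicing = splicing)
  sim_dir <- file.path(out_dir, "inputs")
  write_simulation(sim, sim_dir)
  # consume our own files to exercise the full round trip
  geno <- suppressMessages(read_vcf(file.path(sim_dir, "genotypes.vcf")))
  expr <- read_phenotype_bed(file.path(sim_dir, "expression.bed"))
  samples <- read_sample_table(file.path(sim_dir, "samples.tsv"))
  tick("simulate", nrow(geno$variants))

  prep <- prepare_phenotypes(expr, samples, n_pcs = n_pcs)
  tick("prep", nrow(prep$pheno$values))

  vp <- partition_variance(prep$pheno, samples)
  write_stage_tsv(vp, out_dir, "varpart")
  gv <- group_variance_test(prep$pheno, samples)
  tick("varpart", nrow(vp))

  scan <- scan_study(prep$pheno, geno, n_perm = n_perm, fdr = fdr,
                     seed = config$seed)
  write_stage_tsv(scan$genes, out_dir, "egenes")
  tick("scan", nrow(scan$genes))

  egenes <- scan$genes$gene_id[scan$genes$is_egene]
  feats <- prep$pheno$features
  fits <- list(); set_rows <- list()
  for (g in egenes) {
    i <- match(g, feats$feature_id)
    fm <- finemap_feature(prep$pheno$values[i, ], geno, feats$chrom[i],
                          feats$tss[i], L = L)
    fits[[g]] <- fm$fit
    if (nrow(fm$sets) > 0) {
      flat <- tidyr::unnest(fm$sets[, c("set_id", "purity", "lead_variant_id",
                                        "variants")],
                            cols = dplyr::all_of("variants"))
      flat$gene_id <- g
      set_rows[[g]] <- flat
    }
  }
  sets <- dplyr::bind_rows(set_rows)
  if (nrow(sets) > 0) write_stage_tsv(sets, out_dir, "credible_sets")
  tick("finemap", nrow(sets))

  lin <- afc_expression(expr)
  afc_rows <- list()
  if (nrow(sets) > 0) {
    for (g in unique(sets$gene_id)) {
      leads <- unique(sets$lead_variant_id[sets$gene_id == g])
      Gl <- t(geno$dosages[match(leads, geno$variants$variant_id), , drop = FALSE])
      colnames(Gl) <- leads
      a <- tryCatch(afc_conditional(lin[g, ], Gl, n_boot = 0),
                    error = function(e) NULL)
      if (!is.null(a)) { a$gene_id <- g; afc_rows[[g]] <- a }
    }
  }
  afc <- dplyr::bind_rows(afc_rows)
  if (nrow(afc) > 0) write_stage_tsv(afc, out_dir, "afc")
  tick("afc", nrow(afc))

  ga <- group_af(geno, samples)
  focal <- samples$continental_group[1]
  fst <- fst_focal(geno, samples,
                   variant_ids = unique(sets$lead_variant_id))
  de <- nb_de(expr, samples, focal)
  pop_out <- NULL
  if (nrow(sets) > 0) {
    lead_tbl <- dplyr::distinct(sets[, c("gene_id", "lead_variant_id")])
    lead_tbl <- dplyr::rename(lead_tbl, variant_id = "lead_variant_id")
    lead_tbl <- dplyr::inner_join(lead_tbl, fst, by = "variant_id")
    pop_out <- tryCatch(fst_by_de_decile(lead_tbl, de), error = function(e) NULL)
  }
  write_stage_tsv(de, out_dir, "differential_expression")
  write_stage_tsv(ga$flags, out_dir, "af_flags")
  tick("popdiff", nrow(de))

  het_rows <- list()
  if (nrow(sets) > 0) {
    elig <- eligibility_filter(ga$af)
    covs <- prep$covariates
    for (g in unique(sets$gene_id)) {
      i <- match(g, feats$feature_id)
      y <- prep$pheno$values[i, ]
      leads <- unique(sets$lead_variant_id[sets$gene_id == g])
      leads <- leads[leads %in% elig$variant_id[elig$eligible]]
      if (length(leads) == 0) next
      Gl <- t(geno$dosages[match(leads, geno$variants$variant_id), , drop = FALSE])
      colnames(Gl) <- leads
      nom_g <- scan$nominal[scan$nominal$feature_id == g, ]
      top <- nom_g$variant_id[which.min(nom_g$p)]
      gtop <- geno$dosages[match(top, geno$variants$variant_id), ]
      r1 <- tryCatch(interaction_test_single(y, gtop, samples, covs),
                     error = function(e) NULL)
      if (!is.null(r1)) {
        r1$gene_id <- g; r1$focal_variant <- top
        r1$n_credible_sets <- length(leads)
        het_rows[[length(het_rows) + 1]] <- r1
      }
      for (k in seq_along(leads)) {
        r2 <- tryCatch(interaction_test_multi(y, Gl, k, samples, covs),
                       error = function(e) NULL)
        if (!is.null(r2)) {
          r2$gene_id <- g; r2$focal_variant <- leads[k]
          r2$n_credible_sets <- length(leads)
          het_rows[[length(het_rows) + 1]] <- r2
        }
      }
    }
  }
  het <- dplyr::bind_rows(het_rows)
  het_summary <- if (nrow(het) > 0) bonferroni_summary(het) else NULL
  if (nrow(het) > 0) write_stage_tsv(het_summary$results, out_dir, "interactions")
  tick("hetero", nrow(het))

  enr <- NULL
  if (nrow(sets) > 0) {
    gm <- attr(sim$genotypes, "gene_map")
    promoters <- tibble::tibble(chrom = gm$chrom, start = gm$tss - 2000L,
                                end = gm$tss + 2000L)
    vmeta <- geno$variants
    vmeta$maf <- pmin(rowMeans(geno$dosages) / 2, 1 - rowMeans(geno$dosages) / 2)
    gene_map <- attr(sim$genotypes, "af")
    vmeta$tss_distance <- vmeta$pos -
      gm$tss[match(gene_map$gene_id[match(vmeta$variant_id, gene_map$variant_id)],
                   gm$gene_id)]
    lead_ids <- unique(sets$lead_variant_id)
    leads_tb <- vmeta[vmeta$variant_id %in% lead_ids & vmeta$maf > 0, ]
    pool_tb <- vmeta[!vmeta$variant_id %in% lead_ids & vmeta$maf >= 0.01, ]
    enr <- tryCatch(
      enrichment_scan(leads_tb, pool_tb, list(promoter = promoters),
                      n_draws = 200, seed = config$seed),
      error = function(e) NULL)
    if (!is.null(enr) && nrow(enr) > 0) write_stage_tsv(enr, out_dir, "enrichment")
  }
  tick("enrich", if (is.null(enr)) 0 else nrow(enr))

  col_rows <- list()
  if (splicing && length(fits) > 0) {
    spl <- read_phenotype_bed(file.path(sim_dir, "splicing.bed"), "ratios")
    spl_prep <- residualize(inverse_normal_transform(spl), prep$covariates)
    for (g in names(fits)) {
      ji <- which(spl_prep$features$gene_id == g)
      if (length(ji) == 0) next
      i <- match(g, feats$feature_id)
      fm_s <- tryCatch(
        finemap_feature(spl_prep$values[ji[1], ], geno, feats$chrom[i],
                        feats$tss[i], L = L),
        error = function(e) NULL)
      if (is.null(fm_s) || nrow(fm_s$sets) == 0) next
      cc <- tryCatch(susie_coloc(fits[[g]], fm_s$fit), error = function(e) NULL)
      if (!is.null(cc) && nrow(cc) > 0) {
        cc$gene_id <- g
        col_rows[[g]] <- cc
      }
    }
  }
  col <- dplyr::bind_rows(col_rows)
  if (nrow(col) > 0) write_stage_tsv(col, out_dir, "coloc")
  tick("coloc", nrow(col))

  manifest$finished <- format(Sys.time())
  manifest$package_version <- as.character(utils::packageVersion("divqtl"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, varpart = vp, group_variance = gv, scan = scan,
                 sets = sets, afc = afc, de = de, af = ga,
                 fst_by_decile = pop_out, hetero = het_summary,
                 enrichment = enr, coloc = col, manifest = manifest))
}
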