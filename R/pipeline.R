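## End-to-end orchestration: genotype QC -> population PCs -> normalization and
## expressed sets -> hidden factors -> per-condition eQTL scans -> hotspots ->
## reQTL candidates / interaction tests / classification -> heo-eGene
## detection -> footprint integration, plus evaluation against planted truth.

#' Pipeline parameter defaults
#'
#' @param maf_min,het_max,max_missing Variant filters.
#' @param n_pcs Genotype principal components used as covariates.
#' @param n_factors Hidden expression factors per condition (and for the
#'   stacked interaction-model covariates). The study-scale analogue is 25;
#'   the default 5 suits panels of ~100-150 genotypes.
#' @param cpm_min,frac_min Expressed-gene rule (CPM > cpm_min in >= frac_min
#'   of genotypes).
#' @param de_p_adj,de_lfc Paired differential-expression thresholds.
#' @param eqtl_p_adj BH threshold for association hits.
#' @param cis_bp cis window (1 Mb, inclusive).
#' @param bh_strata `"separate"` or `"joint"` BH over cis/trans strata.
#' @param r2_ld High-LD threshold for candidate deduplication.
#' @param reqtl_alpha Bonferroni threshold for reQTL calls.
#' @param flank_bp Rescan window beyond the gene body.
#' @param fp_flank_bp Footprint assignment flank.
#' @param top_k Top-variant rule for footprint overlap.
#' @param recall_occupancy Recompute footprint statuses from replicate counts
#'   (default FALSE: trust provided statuses).
#' @param ld_window,ld_step,ld_r2_max LD pruning parameters (pruning is
#'   reported but PCs are computed on all filtered variants).
#' @return Named list of parameters.
#' @export
pipeline_params <- function(maf_min = 0.1, het_max = 0.1, max_missing = 0,
                            n_pcs = 5L, n_factors = 5L, cpm_min = 1,
                            frac_min = 0.10, de_p_adj = 0.01, de_lfc = 1,
                            eqtl_p_adj = 0.01, cis_bp = 1e6,
                            bh_strata = "separate", r2_ld = 0.8,
                            reqtl_alpha = 0.01, flank_bp = 1000L,
                            fp_flank_bp = 2000L, top_k = 3L,
                            recall_occupancy = FALSE, ld_window = 50L,
                            ld_step = 5L, ld_r2_max = 0.99,
                            hotspot_covariates = c("pcs_only", "factors")) {
  out <- as.list(environment())
  out$hotspot_covariates <- match.arg(hotspot_covariates)
  out
}

## inverse-normal transform rows of a matrix
int_rows <- function(m) {
  out <- t(apply(m, 1, inverse_normal_transform))
  dimnames(out) <- dimnames(m)
  out
}

#' Run the full response-eQTL pipeline
#'
#' @param cohort List with `G` ([genotype_matrix()]), `genes`, `pair`
#'   ([expression_pair()]) and optionally `footprints` and `truth`, e.g. from
#'   [simulate_cohort()] or assembled from files via the readers.
#' @param params [pipeline_params()].
#' @param seed Seed for the candidate-selection tie-breaks.
#' @param out_dir Optional directory; stage tables are written as TSV.
#' @return A report list with every stage's table (see vignette).
#' @export
run_pipeline <- function(cohort, params = pipeline_params(), seed = 1L,
                         out_dir = NULL) {
  G0 <- cohort$G
  genes <- cohort$genes
  pair <- cohort$pair
  stopifnot(identical(rownames(G0$dosage), pair$sample_ids))

  ## genotype QC + population structure
  G <- variant_filter(G0, maf_min = params$maf_min, het_max = params$het_max,
                      max_missing = params$max_missing, impute = TRUE)
  pcs <- compute_pcs(G, n_components = params$n_pcs)
  pruned_ids <- ld_prune(G, window = params$ld_window, step = params$ld_step,
                         r2_max = params$ld_r2_max)

  ## expression: expressed sets, DE, consistent upregulation
  sets <- expressed_gene_sets(pair, cpm_min = params$cpm_min,
                              frac_min = params$frac_min)
  tested_genes <- union(sets$control, sets$heat)
  de <- paired_de(pair, genes = tested_genes, p_adj_max = params$de_p_adj,
                  lfc_min = params$de_lfc)
  cons_up <- consistent_upregulation(pair, genes = tested_genes)

  ## transformed expression + hidden factors per condition
  expr_c <- pair$cpm_control[sets$control, , drop = FALSE]
  expr_h <- pair$cpm_heat[sets$heat, , drop = FALSE]
  tc <- int_rows(expr_c)
  th <- int_rows(expr_h)
  fac_c <- infer_hidden_factors(log2(expr_c + 1), k = params$n_factors,
                                known_covariates = pcs)
  fac_h <- infer_hidden_factors(log2(expr_h + 1), k = params$n_factors,
                                known_covariates = pcs)

  ## per-condition scans and hotspots
  hits_c <- scan_associations(tc, G, cbind(pcs, fac_c), genes,
                              condition = "control",
                              p_adj_max = params$eqtl_p_adj,
                              cis_bp = params$cis_bp,
                              bh_strata = params$bh_strata)
  hits_h <- scan_associations(th, G, cbind(pcs, fac_h), genes,
                              condition = "heat",
                              p_adj_max = params$eqtl_p_adj,
                              cis_bp = params$cis_bp,
                              bh_strata = params$bh_strata)
  ## hidden-factor covariates absorb broad trans effects, so the hotspot scan
  ## defaults to structure PCs only (see vignette)
  if (params$hotspot_covariates == "pcs_only") {
    th_c <- scan_associations(tc, G, pcs, genes, condition = "control",
                              p_adj_max = params$eqtl_p_adj,
                              cis_bp = params$cis_bp,
                              bh_strata = params$bh_strata)
    th_h <- scan_associations(th, G, pcs, genes, condition = "heat",
                              p_adj_max = params$eqtl_p_adj,
                              cis_bp = params$cis_bp,
                              bh_strata = params$bh_strata)
  } else {
    th_c <- hits_c; th_h <- hits_h
  }
  hotspots <- rbind(cbind(detect_hotspots(th_c), condition = "control"),
                    cbind(detect_hotspots(th_h), condition = "heat"))

  ## interaction model over common genes; stacked-matrix factors as covariates
  common <- sets$common
  stacked <- cbind(log2(pair$cpm_control[common, , drop = FALSE] + 1),
                   log2(pair$cpm_heat[common, , drop = FALSE] + 1))
  pcs2 <- rbind(pcs, pcs)
  fac_stacked <- infer_hidden_factors(stacked, k = params$n_factors,
                                      known_covariates = pcs2)
  lmm_cov <- cbind(pcs2, fac_stacked)
  tc_common <- int_rows(pair$cpm_control[common, , drop = FALSE])
  th_common <- int_rows(pair$cpm_heat[common, , drop = FALSE])
  candidates <- select_candidates(hits_c, hits_h, G, genes_common = common,
                                  r2_ld = params$r2_ld, seed = seed)
  fits <- if (nrow(candidates)) {
    fit_candidates(candidates, tc_common, th_common, G, lmm_cov)
  } else cbind(candidates, data.frame())
  calls <- if (nrow(candidates)) call_reqtls(fits, alpha = params$reqtl_alpha)
           else fits
  regenes <- if (nrow(candidates)) classify_regenes(calls, pair, G)
             else classify_regenes(data.frame(gene_id = character(),
                                              variant_id = character(),
                                              is_reqtl = logical()), pair, G)
  heo <- detect_heo_egenes(sets, hits_h, pair, G)
  plasticity <- transcriptome_plasticity(log2(pair$cpm_control + 1),
                                         log2(pair$cpm_heat + 1))

  ## footprint integration
  fp_res <- NULL
  if (!is.null(cohort$footprints)) {
    fp <- cohort$footprints
    if (params$recall_occupancy) fp <- differential_occupancy(fp)
    assignments <- assign_footprints(fp, genes, flank_bp = params$fp_flank_bp)
    up <- de$gene_id[de$up_DEG]
    bg <- setdiff(intersect(common, de$gene_id[!de$up_DEG & !de$down_DEG]), up)
    enr <- if (length(up) && length(bg)) {
      enrichment_vs_background(assignments, up, bg)
    } else NULL
    ## interaction rescans over every reGene window
    cat_by_gene <- stats::setNames(regenes$category, regenes$gene_id)
    rescan <- do.call(rbind, lapply(regenes$gene_id, function(g) {
      r <- rescan_flanking(g, genes, G, tc_common, th_common, lmm_cov,
                           flank_bp = params$flank_bp)
      if (!nrow(r)) return(NULL)
      r$chrom <- G$variants$chrom[match(r$variant_id, G$variants$id)]
      r$pos <- G$variants$pos[match(r$variant_id, G$variants$id)]
      r$category <- cat_by_gene[[g]]
      r
    }))
    tv <- if (!is.null(rescan) && nrow(rescan)) {
      top_variant_overlap(rescan, fp, genes, top_k = params$top_k,
                          category = cat_by_gene)
    } else NULL
    io <- if (!is.null(rescan) && nrow(rescan)) {
      inside_outside_comparison(rescan, fp)
    } else NULL
    ## heo genes ranked by their heat cis associations
    heo_hits <- hits_h[hits_h$klass == "cis" &
                         hits_h$gene_id %in% heo$gene_id, , drop = FALSE]
    tv_heo <- if (nrow(heo_hits)) {
      top_variant_overlap(heo_hits, fp, genes, top_k = params$top_k,
                          category = stats::setNames(heo$class, heo$gene_id))
    } else NULL
    fp_res <- list(footprints = fp, assignments = assignments,
                   enrichment = enr, rescan = rescan, top_variant = tv,
                   top_variant_heo = tv_heo, inside_outside = io)
  }

  report <- list(
    params = params, seed = seed,
    n_variants_input = ncol(G0$dosage), n_variants_filtered = ncol(G$dosage),
    pruned_ids = pruned_ids, pcs = pcs, sets = sets, de = de,
    consistent_up = cons_up, plasticity = plasticity,
    factors_control = fac_c, factors_heat = fac_h,
    factors_stacked = fac_stacked,
    hits_control = hits_c, hits_heat = hits_h, hotspots = hotspots,
    candidates = candidates, fits = calls, regenes = regenes, heo = heo,
    footprint = fp_res,
    summary = NULL)
  egenes_c <- unique(hits_c$gene_id[hits_c$klass == "cis"])
  egenes_h <- unique(hits_h$gene_id[hits_h$klass == "cis"])
  report$summary <- data.frame(
    metric = c("n_samples", "n_variants_filtered", "n_expressed_control",
               "n_expressed_heat", "n_common", "n_heat_only", "n_up_DEG",
               "n_consistent_up", "n_egenes_control", "n_egenes_heat",
               "n_tested_pairs", "n_reqtls", "n_regenes", "n_heo_egenes",
               "n_hotspots"),
    value = c(length(pair$sample_ids), ncol(G$dosage), length(sets$control),
              length(sets$heat), length(common), length(sets$heat_only),
              sum(de$up_DEG), length(cons_up), length(egenes_c),
              length(egenes_h), nrow(candidates),
              sum(calls$is_reqtl %||% FALSE), nrow(regenes), nrow(heo),
              if (nrow(hotspots)) sum(hotspots$is_hotspot) else 0L),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) {
    if (!is.null(x) && is.data.frame(x) && nrow(x)) {
      keep <- !vapply(x, is.list, logical(1))
      data.table::fwrite(x[keep], file.path(out_dir, f), sep = "\t")
    }
  }
  fw(report$summary, "summary.tsv")
  fw(report$de, "differential_expression.tsv")
  fw(report$hits_control, "eqtl_hits_control.tsv")
  fw(report$hits_heat, "eqtl_hits_heat.tsv")
  fw(report$hotspots, "hotspots.tsv")
  fw(report$candidates, "reqtl_candidates.tsv")
  fw(report$fits, "reqtl_fits.tsv")
  fw(report$regenes, "regenes.tsv")
  fw(report$heo, "heo_egenes.tsv")
  fw(report$plasticity, "plasticity.tsv")
  if (!is.null(report$footprint)) {
    fw(report$footprint$inside_outside, "footprint_inside_outside.tsv")
    fw(report$footprint$top_variant$per_category, "footprint_top_variant.tsv")
  }
  invisible(out_dir)
}

#' Compare pipeline calls with planted truth
#'
#' @param report Output of [run_pipeline()].
#' @param truth Truth table from the simulator.
#' @return data.frame of per-class metrics: reQTL sensitivity and false
#'   discovery proportion, reGene category accuracy, heo recovery and class
#'   accuracy, cis-eGene sensitivity, hotspot recovery.
#' @export
evaluate_against_truth <- function(report, truth) {
  if (!all(report$regenes$gene_id %in% truth$gene_id)) {
    stop("gene ids in report do not match the truth table")
  }
  reqtl_classes <- c("reqtl_RefHeat", "reqtl_RefControl",
                     "reqtl_AltHeat", "reqtl_AltControl")
  planted_reqtl <- truth$gene_id[truth$class %in% reqtl_classes]
  called <- unique(report$fits$gene_id[report$fits$is_reqtl %||% FALSE])
  sens <- if (length(planted_reqtl)) {
    mean(planted_reqtl %in% called)
  } else NA_real_
  fdp <- if (length(called)) mean(!(called %in% planted_reqtl)) else NA_real_

  rg <- report$regenes
  rg_truth <- truth$class[match(rg$gene_id, truth$gene_id)]
  is_planted <- rg_truth %in% reqtl_classes
  cat_acc <- if (any(is_planted)) {
    mean(paste0("reqtl_", rg$category[is_planted]) == rg_truth[is_planted])
  } else NA_real_

  planted_heo <- truth$gene_id[truth$class %in% c("heo_RefHeat", "heo_AltHeat")]
  heo_rec <- if (length(planted_heo)) {
    mean(planted_heo %in% report$heo$gene_id)
  } else NA_real_
  hh <- report$heo[report$heo$gene_id %in% planted_heo, , drop = FALSE]
  heo_acc <- if (nrow(hh)) {
    mean(paste0("heo_", hh$class) ==
           truth$class[match(hh$gene_id, truth$gene_id)])
  } else NA_real_

  planted_cis <- truth$gene_id[truth$class %in% c("cis_only", reqtl_classes)]
  egenes <- union(report$hits_control$gene_id[report$hits_control$klass == "cis"],
                  report$hits_heat$gene_id[report$hits_heat$klass == "cis"])
  cis_sens <- if (length(planted_cis)) mean(planted_cis %in% egenes) else NA_real_

  regs <- attr(truth, "regulators")
  hot_rec <- NA_real_
  if (!is.null(regs) && length(regs) && nrow(report$hotspots)) {
    hot <- report$hotspots[report$hotspots$is_hotspot, , drop = FALSE]
    hot_rec <- mean(vapply(regs, function(vid) {
      any(grepl(paste0("^S"), vid)) &&
        any(hot$chrom == sub("^S(\\d+)_.*", "chr\\1", vid) &
              hot$bin_start <= as.integer(sub(".*_", "", vid)) - 1 &
              hot$bin_start + 10000 > as.integer(sub(".*_", "", vid)) - 1)
    }, logical(1)))
  }
  data.frame(
    metric = c("reqtl_sensitivity", "reqtl_fdp", "regene_category_accuracy",
               "heo_recovery", "heo_class_accuracy", "cis_egene_sensitivity",
               "hotspot_recovery"),
    value = c(sens, fdp, cat_acc, heo_rec, heo_acc, cis_sens, hot_rec),
    stringsAsFactors = FALSE)
}
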