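test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_cis = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(frac_cis = 0.9, frac_reqtl = 0.2), "sum")
  expect_error(sim_config(fst = 0.7), "fst")
  expect_error(sim_config(n_variants = 10, ld_block_size = 20),
               "ld_block_size")
})

test_that("genotype generation is deterministic and respects its contracts", {
  cfg <- sim_config(n_samples = 40, n_variants = 400, n_genes = 80, seed = 3)
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1$dosage %in% c(0L, 1L, 2L)))
  v <- g1$variants
  expect_false(is.unsorted(order(v$chrom, v$pos)))
  for (ch in unique(v$chrom)) expect_false(is.unsorted(v$pos[v$chrom == ch]))
  expect_lt(mean(g1$dosage == 1), 0.05)  # near-homozygous
  expect_gt(mean(v$is_indel), 0.03)      # some InDels flagged
})

test_that("within-block r^2 is 1 at within_block_r = 1 and blocks decorrelate", {
  cfg <- sim_config(n_samples = 80, n_variants = 200, n_genes = 40,
                    within_block_r = 1, residual_het_rate = 0,
                    n_trans_hotspots = 0, seed = 5)
  G <- generate_genotypes(cfg)
  d <- G$dosage[, 1:20]  # first LD block of chromosome 1
  cc <- suppressWarnings(cor(d))
  expect_true(all(abs(cc[!is.na(cc)]^2 - 1) < 1e-12))

  cfg2 <- sim_config(n_samples = 100, n_variants = 400, n_genes = 40,
                     n_subpops = 1, fst = 0.01, n_trans_hotspots = 0, seed = 6)
  G2 <- generate_genotypes(cfg2)
  set.seed(1)
  r2 <- replicate(100, {
    i <- sample.int(100, 1)            # block index
    v1 <- (i - 1) %% 20 + sample.int(20, 1)
    v2 <- v1
    while (ceiling(v2 / 20) == ceiling(v1 / 20)) v2 <- sample.int(400, 1)
    suppressWarnings(pairwise_r2(G2$dosage[, v1], G2$dosage[, v2]))
  })
  expect_lt(mean(r2), 0.05)
})

test_that("gene models are non-overlapping with strand-consistent TSS", {
  cfg <- sim_config(n_samples = 20, n_variants = 200, n_genes = 60, seed = 4)
  genes <- generate_gene_models(cfg)
  expect_equal(nrow(genes), 60)
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  minus <- genes[genes$strand == "-", ][1, ]
  expect_equal(minus$tss, minus$end)
  expect_equal(minus$tts, minus$start)
  expect_error(generate_gene_models(sim_config(n_genes = 5000, seed = 1,
                                               frac_reqtl = 0, frac_heo = 0)),
               "packed")
})

test_that("promoter placement puts causal variants upstream of the TSS", {
  cfg <- sim_config(n_samples = 60, n_variants = 3000, n_genes = 100,
                    frac_cis = 0.2, frac_reqtl = 0, frac_heo = 0,
                    n_trans_hotspots = 0, seed = 8)
  G <- generate_genotypes(cfg)
  genes <- generate_gene_models(cfg)
  tr <- generate_expression(G, genes, cfg, placement = "promoter")$truth
  planted <- tr[tr$class == "cis_only", ]
  v <- G$variants
  for (i in seq_len(nrow(planted))) {
    g <- genes[genes$gene_id == planted$gene_id[i], ]
    pos <- v$pos[v$id == planted$causal_variant[i]]
    dist <- if (g$strand == "+") g$tss - pos else pos - g$tss
    expect_gt(dist, 0)
    expect_lte(dist, 2000)
  }
})

test_that("expression generator plants classes that satisfy their definitions", {
  coh <- small_cohort()
  tr <- coh$truth
  expect_identical(
    generate_expression(coh$G, coh$genes, coh$config)$pair$counts_heat,
    coh$pair$counts_heat)  # determinism
  ## planted causal variants exist with MAF >= 0.15
  st <- variant_stats(coh$G)
  causal <- tr$causal_variant[!is.na(tr$causal_variant)]
  expect_true(all(causal %in% coh$G$variants$id))
  expect_true(all(st$maf[match(causal, st$id)] >= 0.15))
  ## reQTL classes satisfy the classification invariants by construction
  th <- (tr$beta_heat - tr$beta_control)
  for (i in which(tr$class == "reqtl_AltHeat")) {
    L_ref <- tr$activation_delta[i]
    L_alt <- tr$activation_delta[i] + 2 * th[i]
    expect_gt(abs(L_alt), abs(L_ref))
    expect_gt(L_alt, 0)
    expect_gte(abs(th[i]), 1)
  }
  ## null genes show no condition effect in mean CPM
  nulls <- tr$gene_id[tr$class == "null"]
  lfc <- log2((rowMeans(coh$pair$cpm_heat[nulls, ]) + 1) /
                (rowMeans(coh$pair$cpm_control[nulls, ]) + 1))
  expect_lt(stats::median(abs(lfc)), 0.2)
})

test_that("near-zero dispersion and equal library sizes give flat CPM", {
  cfg <- sim_config(n_samples = 40, n_variants = 400, n_genes = 50,
                    frac_cis = 0, frac_reqtl = 0, frac_heo = 0,
                    frac_consistent_up = 0, n_trans_hotspots = 0,
                    nb_dispersion = 1e-4, libsize_range = c(1e6, 1e6),
                    n_hidden_factors = 0, seed = 9)
  G <- generate_genotypes(cfg)
  genes <- generate_gene_models(cfg)
  pair <- generate_expression(G, genes, cfg)$pair
  ## remove the per-genotype random intercept by looking at one high-expressed
  ## gene across conditions: heat/control ratio per genotype is ~1
  hi <- which.max(rowMeans(pair$cpm_control))
  ratio <- pair$cpm_heat[hi, ] / pair$cpm_control[hi, ]
  ## only counting (Poisson-level) noise remains
  expect_lt(stats::sd(ratio) / mean(ratio), 3 / sqrt(mean(pair$counts_control[hi, ])))
})

test_that("footprint planting covers causal variants at p_true = 1 only", {
  cfg <- sim_config(n_samples = 60, n_variants = 1500, n_genes = 200, seed = 10)
  G <- generate_genotypes(cfg)
  genes <- generate_gene_models(cfg)
  truth <- generate_expression(G, genes, cfg)$truth
  up <- truth[truth$class %in% c("reqtl_RefHeat", "reqtl_AltHeat",
                                 "heo_RefHeat", "heo_AltHeat"), ]
  covered <- function(fp) {
    v <- G$variants[match(up$causal_variant, G$variants$id), ]
    vapply(seq_len(nrow(v)), function(i) {
      any(fp$chrom == v$chrom[i] & fp$status == "heat_enriched" &
            fp$start <= v$pos[i] - 1 & fp$end > v$pos[i] - 1)
    }, logical(1))
  }
  fp1 <- generate_footprints(truth, genes, cfg, p_true = 1, G = G)
  expect_true(all(covered(fp1)))
  expect_true(all(fp1$start < fp1$end))
  expect_true(all(fp1$end <= cfg$chrom_length_bp))
  ## p_true = 0: only chance coverage from background footprints
  hit0 <- mean(replicate(5, {
    cfg0 <- sim_config(n_samples = 60, n_variants = 1500, n_genes = 200,
                       seed = sample.int(1e6, 1))
    G0 <- generate_genotypes(cfg0)
    gn0 <- generate_gene_models(cfg0)
    t0 <- generate_expression(G0, gn0, cfg0)$truth
    fp0 <- generate_footprints(t0, gn0, cfg0, p_true = 0, G = G0)
    u0 <- t0[t0$class %in% c("reqtl_RefHeat", "reqtl_AltHeat",
                             "heo_RefHeat", "heo_AltHeat"), ]
    v0 <- G0$variants[match(u0$causal_variant, G0$variants$id), ]
    mean(vapply(seq_len(nrow(v0)), function(i) {
      any(fp0$chrom == v0$chrom[i] & fp0$status == "heat_enriched" &
            fp0$start <= v0$pos[i] - 1 & fp0$end > v0$pos[i] - 1)
    }, logical(1)))
  }))
  expect_lt(hit0, 0.05)
})

test_that("median footprint width is near 34 bp", {
  coh <- small_cohort()
  expect_lt(abs(stats::median(coh$footprints$end - coh$footprints$start) - 34), 4)
})
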