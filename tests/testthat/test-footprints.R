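test_that("fragment centering forces 20-bp windows inside the fragment", {
  fr <- data.frame(chrom = "chr1",
                   start = c(100, 0, 100, 50),
                   end = c(131, 81, 130, 60))  # 31, 81 (dropped), 30, 10 (dropped)
  out <- center_fragments(fr, seed = 1)
  expect_equal(nrow(out), 2)
  expect_equal(out$start[1], 105)  # odd length 31: mid 115 -> [105, 125)
  expect_equal(out$end[1], 125)
  expect_true(all(out$end - out$start == 20))
  ## even length 30: one of two middles, reproducible per seed
  o1 <- center_fragments(fr, seed = 7)
  o2 <- center_fragments(fr, seed = 7)
  expect_identical(o1, o2)
  expect_true(o1$start[2] %in% c(104, 105))
  ## windows never leave the fragment
  set.seed(2)
  fr2 <- data.frame(chrom = "chr1", start = s <- sample(1e5, 200),
                    end = s + sample(20:80, 200, TRUE))
  o <- center_fragments(fr2, seed = 3)
  ok <- mapply(function(os, oe) {
    any(fr2$start <= os & fr2$end >= oe)
  }, o$start, o$end)
  expect_true(all(ok))
})

test_that("differential occupancy is symmetric and finds planted shifts", {
  coh <- small_cohort()
  fp <- coh$footprints
  res <- differential_occupancy(fp)
  planted_up <- fp$status == "heat_enriched"
  expect_gte(mean(res$status[planted_up] == "heat_enriched"), 0.8)
  ## stable intervals are essentially never called enriched (the library
  ## composition shift from the planted 4x mass can only bias toward depleted)
  expect_lte(mean(res$status[fp$status == "stable"] == "heat_enriched"), 0.02)
  ## identical replicate counts -> all stable
  fp2 <- fp
  fp2[paste0("heat_", 1:3)] <- fp2[paste0("ctrl_", 1:3)]
  expect_true(all(differential_occupancy(fp2)$status == "stable"))
  ## swapping condition labels swaps enriched and depleted
  fp3 <- fp
  fp3[c(paste0("ctrl_", 1:3), paste0("heat_", 1:3))] <-
    fp[c(paste0("heat_", 1:3), paste0("ctrl_", 1:3))]
  r3 <- differential_occupancy(fp3)
  expect_identical(res$status == "heat_enriched", r3$status == "heat_depleted")
  expect_identical(res$status == "stable", r3$status == "stable")
  expect_error(differential_occupancy(fp[1:4]), "replicate")
})

test_that("footprint assignment respects coordinates, strand and boundaries", {
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                      start = c(10000, 50000), end = c(12000, 52000),
                      strand = c("+", "-"), tss = c(10000, 52000),
                      tts = c(12000, 50000))
  fp <- data.frame(
    chrom = "chr1",
    ##      just misses     promoter+  promoter-(downstream) far
    start = c(7979,          9000,      53000,               30000),
    end   = c(7999,          9040,      53040,               30040),
    status = c("stable", "heat_enriched", "heat_enriched", "heat_enriched"),
    stringsAsFactors = FALSE)
  a <- assign_footprints(fp, genes, flank_bp = 2000)
  ## fp1 ends exactly at start - 2000 in half-open coords: no shared base
  expect_equal(a$n_flank[1], 1)       # only fp2 overlaps the plus-gene flank
  expect_true(a$has_heat_enriched[1])
  expect_equal(a$n_promoter[1], 1)    # fp2 in [8000, 9999]
  ## minus-strand promoter lies at higher coordinates
  expect_equal(a$n_promoter[2], 1)
  expect_true(a$has_heat_enriched[2])
  expect_equal(a$n_body, c(0, 0))
  ## translation invariance
  sh <- 12345L
  fp_s <- fp; fp_s$start <- fp_s$start + sh; fp_s$end <- fp_s$end + sh
  g_s <- genes
  for (col in c("start", "end", "tss", "tts")) g_s[[col]] <- g_s[[col]] + sh
  a_s <- assign_footprints(fp_s, g_s, flank_bp = 2000)
  expect_identical(a[c("n_flank", "n_promoter", "n_body", "has_heat_enriched")],
                   a_s[c("n_flank", "n_promoter", "n_body", "has_heat_enriched")])
})

test_that("generated promoter footprints map back to their seeding genes", {
  coh <- small_cohort()
  a <- assign_footprints(coh$footprints, coh$genes, flank_bp = 2000)
  ## every gene got 1-3 background footprints near its TSS
  expect_gte(mean(a$n_flank >= 1), 0.95)
})

test_that("enrichment test wraps the Fisher oracle and rejects overlap", {
  assignments <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    has_heat_enriched = c(rep(TRUE, 30), rep(FALSE, 70),
                          rep(TRUE, 10), rep(FALSE, 90)))
  up <- sprintf("g%03d", 1:100)
  bg <- sprintf("g%03d", 101:200)
  res <- enrichment_vs_background(assignments, up, bg)
  expect_equal(unname(res$table[1, ]), c(30, 70))
  expect_equal(res$p, fisher_greater_oracle(matrix(c(30, 10, 70, 90), 2)),
               tolerance = 1e-12)
  expect_error(enrichment_vs_background(assignments, up, up[1]), "disjoint")
  ## identical presence rates are not enriched
  up2 <- sprintf("g%03d", c(1:10, 31:50))    # 10 with, 20 without
  bg2 <- sprintf("g%03d", c(11:20, 51:70))   # 10 with, 20 without
  res0 <- enrichment_vs_background(assignments, up2, bg2)
  expect_gte(res0$p, 0.5)
})

test_that("top-variant overlap ranks by p with TSS tie-break and half-open test", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000, end = 3000,
                      strand = "+", tss = 1000, tts = 3000)
  fp <- data.frame(chrom = "chr1", start = c(500), end = c(520),
                   status = "heat_enriched", stringsAsFactors = FALSE)
  res <- data.frame(gene_id = "g1", variant_id = c("a", "b", "c", "d"),
                    chrom = "chr1", pos = c(501, 521, 2000, 2500),
                    p = c(0.5, 0.001, 0.001, 0.001), stringsAsFactors = FALSE)
  ## top 3 by p: b, c, d. b sits at the interval end coordinate (0-based
  ## point 520 vs half-open [500, 520)): outside. a (truly inside) ranks 4th
  ## on p and is not reached with top_k = 3.
  tv <- top_variant_overlap(res, fp, genes, top_k = 3)
  expect_false(tv$per_gene$flagged)
  ## with top_k = 4, the inside variant is reached
  tv4 <- top_variant_overlap(res, fp, genes, top_k = 4)
  expect_true(tv4$per_gene$flagged)
  ## variant at position 501 -> 0-based 500 = interval start: inside
  res2 <- res; res2$p[1] <- 1e-6
  expect_true(top_variant_overlap(res2, fp, genes, top_k = 1)$per_gene$flagged)
})

test_that("inside/outside comparison pools -log10 p and uses the rank-sum test", {
  fp <- data.frame(chrom = "chr1", start = 100, end = 200,
                   status = "heat_enriched", stringsAsFactors = FALSE)
  rescan <- data.frame(
    gene_id = "g1", chrom = "chr1",
    pos = c(150, 160, 170, 500, 600, 700),
    p_raw = c(1e-6, 1e-5, 1e-4, 0.1, 0.2, 0.5),
    category = "RefHeat", stringsAsFactors = FALSE)
  res <- inside_outside_comparison(rescan, fp)
  expect_equal(res$n_in, 3)
  expect_equal(res$n_out, 3)
  expect_equal(res$p, 0.1)  # all inside exceed all outside, 3 vs 3, exact
  ## identical values give p = 1
  rescan$p_raw <- 0.01
  expect_equal(inside_outside_comparison(rescan, fp)$p, 1)
  ## empty inside group -> not computable
  rescan2 <- rescan; rescan2$pos <- rescan2$pos + 1e4
  expect_false(inside_outside_comparison(rescan2, fp)$computable)
})

test_that("relative position classes are strand-symmetric", {
  gplus <- list(chrom = "chr1", start = 5000, end = 8000, strand = "+",
                tss = 5000, tts = 8000)
  gminus <- list(chrom = "chr1", start = 5000, end = 8000, strand = "-",
                 tss = 8000, tts = 5000)
  r <- relative_position(4500, gplus)
  expect_equal(r$dist_tss, -500)
  expect_equal(r$class, "proximal_upstream")
  r2 <- relative_position(8500, gminus)  # mirror case
  expect_equal(r2$dist_tss, -500)
  expect_equal(r2$class, "proximal_upstream")
  expect_equal(relative_position(5000, gplus)$class, "genic")
  expect_equal(relative_position(5000, gplus)$dist_tss, 0)
  expect_equal(relative_position(1000, gplus)$class, "distal_upstream")
  expect_equal(relative_position(9000, gplus)$class, "proximal_downstream")
  expect_equal(relative_position(20000, gplus)$class, "distal_downstream")
  expect_error(relative_position(100, gplus, chrom = "chr2"), "different")
})
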