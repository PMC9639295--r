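#!/usr/bin/env Rscript
## Stage 6: TF-footprint integration.
## Re-derives differential occupancy from the 3+3 replicate counts (Welch t on
## log2 interval CPM, BH < 0.05), assigns footprints to gene flanks/promoters,
## tests enrichment of heat-enriched footprints near upregulated genes, and
## compares interaction effects for rescanned variants inside vs outside
## heat-enriched footprints per reGene category.

library(reqtlmap)

G <- variant_filter(read_dosage_tsv("results/cohort/genotypes_dosage.tsv"))
genes <- read_gene_models("results/cohort/genes.tsv")
pair <- expression_pair(read_counts_tsv("results/cohort/counts_control.tsv"),
                        read_counts_tsv("results/cohort/counts_heat.tsv"))
fp <- read_footprints_bed("results/cohort/footprints.bed")
de <- read.delim("results/expression/differential_expression.tsv")
regenes <- read.delim("results/reqtl/regenes.tsv")
dir.create("results/footprints", showWarnings = FALSE, recursive = TRUE)

fp <- differential_occupancy(fp, fdr_max = 0.05)
cat("footprint statuses after the occupancy test:\n")
print(table(fp$status))

assignments <- assign_footprints(fp, genes, flank_bp = 2000)
sets <- expressed_gene_sets(pair)
up <- de$gene_id[de$up_DEG]
bg <- setdiff(intersect(sets$common, de$gene_id[!de$up_DEG & !de$down_DEG]), up)
enr <- enrichment_vs_background(assignments, up, bg)
cat("heat-enriched footprints near", sum(enr$table[1, 1]), "of", length(up),
    "upregulated genes vs", enr$table[2, 1], "of", length(bg),
    "background genes; Fisher p =", format(enr$p, digits = 3), "\n")

## interaction rescans over reGene windows
pcs <- compute_pcs(G, 5)
int_rows <- function(m) {
  out <- t(apply(m, 1, inverse_normal_transform)); dimnames(out) <- dimnames(m)
  out
}
tc <- int_rows(pair$cpm_control[sets$common, ])
th <- int_rows(pair$cpm_heat[sets$common, ])
stacked <- cbind(log2(pair$cpm_control[sets$common, ] + 1),
                 log2(pair$cpm_heat[sets$common, ] + 1))
covs <- cbind(rbind(pcs, pcs),
              infer_hidden_factors(stacked, k = 5,
                                   known_covariates = rbind(pcs, pcs)))
cat_by_gene <- setNames(regenes$category, regenes$gene_id)
rescan <- do.call(rbind, lapply(regenes$gene_id, function(g) {
  r <- rescan_flanking(g, genes, G, tc, th, covs, flank_bp = 1000)
  if (!nrow(r)) return(NULL)
  r$chrom <- G$variants$chrom[match(r$variant_id, G$variants$id)]
  r$pos <- G$variants$pos[match(r$variant_id, G$variants$id)]
  r$category <- cat_by_gene[[g]]
  r
}))
write.table(rescan, "results/footprints/rescan_fits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tv <- top_variant_overlap(rescan, fp, genes, top_k = 3,
                          category = cat_by_gene)
cat("top-3 variant inside a heat-enriched footprint, by category:\n")
print(tv$per_category)
write.table(tv$per_category, "results/footprints/top_variant_by_category.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

io <- inside_outside_comparison(rescan, fp)
cat("inside/outside interaction-effect comparison:\n")
print(io)
write.table(io, "results/footprints/inside_outside.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
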