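#!/usr/bin/env Rscript
## Stage 3: expression normalization and condition comparison.
## Builds the paired CPM object (median-of-ratios against a common reference),
## derives expressed-gene sets (CPM > 1 in >= 10% of genotypes), runs the
## paired Wilcoxon differential test with BH < 0.01 and |log2FC| > 1 calls,
## flags consistently upregulated genes, and scores per-genotype transcriptome
## plasticity (|delta PC1| tertiles).

library(reqtlmap)

counts_c <- read_counts_tsv("results/cohort/counts_control.tsv")
counts_h <- read_counts_tsv("results/cohort/counts_heat.tsv")
pair <- expression_pair(counts_c, counts_h)
dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)

sets <- expressed_gene_sets(pair)
cat("expressed: control", length(sets$control), "heat", length(sets$heat),
    "common", length(sets$common), "heat-only", length(sets$heat_only), "\n")
for (nm in names(sets)) {
  writeLines(sets[[nm]], file.path("results/expression",
                                   paste0("expressed_", nm, ".txt")))
}

de <- paired_de(pair, genes = union(sets$control, sets$heat))
cat("DEGs: up", sum(de$up_DEG), "down", sum(de$down_DEG), "\n")
write.table(de, "results/expression/differential_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cons <- consistent_upregulation(pair, genes = union(sets$control, sets$heat))
cat("consistently upregulated:", length(cons), "\n")
writeLines(cons, "results/expression/consistent_upregulated.txt")

pl <- transcriptome_plasticity(log2(pair$cpm_control + 1),
                               log2(pair$cpm_heat + 1))
write.table(pl, "results/expression/plasticity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("plasticity classes:\n")
print(table(pl$class))
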