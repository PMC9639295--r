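#!/usr/bin/env Rscript
## Stage 5: reQTL detection and responsive-gene classification.
## Selects each common gene's top cis variant per condition (LD-deduplicated),
## fits the paired random-intercept interaction model with 5 PCs + 5 stacked
## hidden factors as covariates, calls reQTLs at Bonferroni-adjusted p < 0.01,
## classifies reGenes by allele and direction, and detects heo-eGenes.

library(reqtlmap)

G <- variant_filter(read_dosage_tsv("results/cohort/genotypes_dosage.tsv"))
genes <- read_gene_models("results/cohort/genes.tsv")
pair <- expression_pair(read_counts_tsv("results/cohort/counts_control.tsv"),
                        read_counts_tsv("results/cohort/counts_heat.tsv"))
hits_c <- read.delim("results/eqtl/hits_control.tsv")
hits_h <- read.delim("results/eqtl/hits_heat.tsv")
dir.create("results/reqtl", showWarnings = FALSE, recursive = TRUE)

pcs <- compute_pcs(G, 5)
sets <- expressed_gene_sets(pair)
int_rows <- function(m) {
  out <- t(apply(m, 1, inverse_normal_transform)); dimnames(out) <- dimnames(m)
  out
}
tc <- int_rows(pair$cpm_control[sets$common, ])
th <- int_rows(pair$cpm_heat[sets$common, ])
stacked <- cbind(log2(pair$cpm_control[sets$common, ] + 1),
                 log2(pair$cpm_heat[sets$common, ] + 1))
fac <- infer_hidden_factors(stacked, k = 5,
                            known_covariates = rbind(pcs, pcs))
covs <- cbind(rbind(pcs, pcs), fac)

cand <- select_candidates(hits_c, hits_h, G, genes_common = sets$common,
                          seed = 1)
cat("tested gene/cis-eQTL pairs:", nrow(cand), "\n")
fits <- fit_candidates(cand, tc, th, G, covs)
calls <- call_reqtls(fits, alpha = 0.01)
cat("reQTLs called:", sum(calls$is_reqtl), "\n")
write.table(calls, "results/reqtl/interaction_fits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

regenes <- classify_regenes(calls, pair, G)
cat("reGene categories:\n")
print(table(regenes$category))
write.table(regenes, "results/reqtl/regenes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

heo <- detect_heo_egenes(sets, hits_h, pair, G)
cat("heo-eGenes:", nrow(heo), "of", length(sets$heat_only),
    "heat-only genes; classes:\n")
print(table(heo$class))
write.table(heo, "results/reqtl/heo_egenes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
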