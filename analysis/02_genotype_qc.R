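#!/usr/bin/env Rscript
## Stage 2: genotype QC and population structure.
## Filters variants (MAF >= 0.1, het <= 0.1, no missing), prunes high-LD pairs
## with the windowed rule (50 variants / step 5 / r^2 0.99), computes the first
## five structure PCs, and picks a diversity-preserving 60-genotype subset by
## Ward clustering (medoid representatives).

library(reqtlmap)

G <- read_dosage_tsv("results/cohort/genotypes_dosage.tsv")
dir.create("results/genotype", showWarnings = FALSE, recursive = TRUE)

Gf <- variant_filter(G, maf_min = 0.1, het_max = 0.1)
cat("variants:", ncol(G$dosage), "->", ncol(Gf$dosage), "after filtering\n")

kept <- ld_prune(Gf)
cat("LD pruning retains", length(kept), "of", ncol(Gf$dosage), "variants\n")
writeLines(kept, "results/genotype/ld_pruned_variants.txt")

pcs <- compute_pcs(Gf, 5)
cat("first five PCs explain",
    sprintf("%.1f%%", 100 * sum(attr(pcs, "explained"))),
    "of dosage variance\n")
write.table(data.frame(sample_id = rownames(pcs), pcs),
            "results/genotype/pcs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

subset60 <- select_diverse_subset(Gf, n_clusters = 60, snps_per_chrom = 1000,
                                  seed = 1)
writeLines(subset60, "results/genotype/diverse_subset.txt")
cat("selected", length(subset60), "cluster representatives\n")
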