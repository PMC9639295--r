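#!/usr/bin/env Rscript
## Stage 1: simulate the study cohort.
## A panel of 120 near-homozygous genotypes (4 subpopulations, Fst 0.1),
## 6,000 variants in 20-variant LD blocks on 3 chromosomes, 1,200 genes with
## planted cis, reQTL, heat-expressed-only, consistently-upregulated and
## trans-hotspot classes, paired control/heat negative-binomial counts, and
## TF-footprint intervals enriched over the causal variants of upregulated
## genes. Writes all inputs plus the truth table under results/cohort/.

library(reqtlmap)

seed <- 1L
cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat("cohort written to results/cohort (seed", seed, ")\n")
cat("samples:", cfg$n_samples, " variants:", cfg$n_variants,
    " genes:", cfg$n_genes, "\n")
cat("planted classes:\n")
print(table(cohort$truth$class))
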