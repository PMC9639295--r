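#!/usr/bin/env Rscript
## Stage 7: end-to-end evaluation against the planted truth.
## Re-runs the orchestrated pipeline on the stage-1 cohort (identical results
## to the stepwise drivers) and scores sensitivity, false-discovery
## proportion, classification accuracy and hotspot recovery per planted class.

library(reqtlmap)

cohort <- list(
  G = read_dosage_tsv("results/cohort/genotypes_dosage.tsv"),
  genes = read_gene_models("results/cohort/genes.tsv"),
  pair = expression_pair(read_counts_tsv("results/cohort/counts_control.tsv"),
                         read_counts_tsv("results/cohort/counts_heat.tsv")),
  footprints = read_footprints_bed("results/cohort/footprints.bed"))
truth <- read.delim("results/cohort/truth.tsv")
## regulator variant ids travel through the truth table
attr(truth, "regulators") <-
  unique(na.omit(truth$causal_variant[truth$class == "trans_target"]))

report <- run_pipeline(cohort, pipeline_params(), seed = 1,
                       out_dir = "results/pipeline")
ev <- evaluate_against_truth(report, truth)
print(ev)
write.table(ev, "results/evaluation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("pipeline stage tables under results/pipeline/\n")
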