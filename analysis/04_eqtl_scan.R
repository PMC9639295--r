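#!/usr/bin/env Rscript
## Stage 4: per-condition eQTL scans and trans-hotspot detection.
## Expression is inverse-normal transformed per condition; scans control for
## 5 structure PCs plus 5 per-condition hidden factors; BH < 0.01 within the
## cis and trans strata separately. Hotspots are detected on PC-only scans
## (hidden-factor correction absorbs broad trans signals) by the
## >= 3-remote-targets / > 10-unique-genes-per-10-kb-bin rule.

library(reqtlmap)

G <- variant_filter(read_dosage_tsv("results/cohort/genotypes_dosage.tsv"))
genes <- read_gene_models("results/cohort/genes.tsv")
pair <- expression_pair(read_counts_tsv("results/cohort/counts_control.tsv"),
                        read_counts_tsv("results/cohort/counts_heat.tsv"))
dir.create("results/eqtl", showWarnings = FALSE, recursive = TRUE)

pcs <- compute_pcs(G, 5)
sets <- expressed_gene_sets(pair)
int_rows <- function(m) {
  out <- t(apply(m, 1, inverse_normal_transform)); dimnames(out) <- dimnames(m)
  out
}

for (cond in c("control", "heat")) {
  expr <- if (cond == "control") pair$cpm_control[sets$control, ]
          else pair$cpm_heat[sets$heat, ]
  tx <- int_rows(expr)
  fac <- infer_hidden_factors(log2(expr + 1), k = 5, known_covariates = pcs)
  hits <- scan_associations(tx, G, cbind(pcs, fac), genes, condition = cond)
  cat(cond, ": ", sum(hits$klass == "cis"), "cis and",
      sum(hits$klass == "trans"), "trans hit records;",
      length(unique(hits$gene_id[hits$klass == "cis"])), "eGenes\n")
  write.table(hits, sprintf("results/eqtl/hits_%s.tsv", cond), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ## PC-only scan for hotspot detection
  hits_pc <- scan_associations(tx, G, pcs, genes, condition = cond)
  hs <- detect_hotspots(hits_pc)
  cat(cond, ":", sum(hs$is_hotspot), "hotspot bins\n")
  write.table(hs, sprintf("results/eqtl/hotspots_%s.tsv", cond), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
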