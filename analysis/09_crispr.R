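#!/usr/bin/env Rscript
# CROP-seq style validation: cell QC, gRNA-to-cell assignment with the
# UMI >= 10 unique-target rule, knockdown quantification, pseudobulk
# differential expression against non-targeting controls, and enrichment
# of the regulator's annotated targets among the DEGs.

source("analysis/00_config.R")

sim <- cohort_and_truth()
genes <- names(sim$truth$module_labels)
# screen the cohort's planted module-1 regulators themselves; their
# annotated targets are de-repressed in knockdown cells
screened <- sim$truth$regulators[1:6]
downstream <- lapply(sim$truth$regulator_targets[screened],
                     function(d) d$target)
cr <- simulate_cropseq(genes, targets = screened,
                       knockdown_fraction = 0.75,
                       downstream_targets = downstream,
                       cells_per_guide = 80, seed = SEED)

qc <- cell_qc(cr$counts)
message("cells passing QC: ", ncol(qc), " / ", ncol(cr$counts))

asg <- assign_grnas(cr$grna_umi, cr$guide_map)
write_tsv(asg, "grna_assignments.tsv")
message("cells with a unique target at UMI >= 10: ",
        sum(!is.na(asg$target)), " / ", nrow(asg))

kd <- do.call(rbind, lapply(names(cr$truth$knockdown_fraction),
                            function(t) {
  kr <- knockdown_ratio(cr$counts, asg, t, cr$replicates)
  data.frame(target = t, mean_ratio = mean(kr$ratio, na.rm = TRUE),
             n_replicates = sum(!is.na(kr$ratio)))
}))
print(kd)
write_tsv(kd, "knockdown_ratios.tsv")

t1 <- names(cr$truth$knockdown_fraction)[1]
de <- pseudobulk_de(cr$counts, asg, t1, cr$replicates)
write_tsv(de, "crispr_pseudobulk_de.tsv")
message("DEGs at FDR < 0.05 for ", t1, ": ", sum(de$fdr < 0.05))

# enrichment hook: predicted targets of the regulator vs DEGs
annot <- simulate_regulator_annotations(sim$truth, fpr = 0)
predicted <- annot$target[annot$regulator == t1]
deg <- de$gene[de$fdr < 0.05 & de$gene != t1]
fe <- fisher_enrichment(deg, predicted, genes)
message(sprintf("predicted-target enrichment for %s: OR %.2f, p %.3g",
                t1, fe$or, fe$p))
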