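#!/usr/bin/env Rscript
# Generate the synthetic cohort and companion datasets, and persist the
# primary inputs in plain-text formats. The cohort emulates nine genetic
# forms plus control, four differentiation days, nested
# individual/line/differentiation replicates, planted co-expression
# modules, a convergence schedule that increasingly shares differential-
# expression effects across forms, CNV dosage genes and repressive
# regulators concentrated in module 1.

source("analysis/00_config.R")

sim <- cohort_and_truth()
print(sim$cohort)

write_cohort(sim$cohort, file.path(RESULTS, "cohort"))
write_truth(sim$truth, file.path(RESULTS, "cohort", "truth.json"))

# module gene sets for downstream enrichment
labels <- sim$truth$module_labels
sets <- split(names(labels)[labels > 0], labels[labels > 0])
names(sets) <- paste0("module", names(sets))
write_gmt(sets, file.path(RESULTS, "module_sets.gmt"))

# motif-scan style regulator annotation; the false-positive rate is per
# candidate (regulator, gene) pair, so 1% already leaves ~10% of genes
# spuriously targeted by at least one of the ten regulators
annot <- simulate_regulator_annotations(sim$truth, fpr = 0.01,
                                        seed = SEED)
write_tsv(annot, "regulator_annotation.tsv")

message("forms: ", paste(unique(sim$cohort$samples$form), collapse = ", "))
message("samples per form/day: ",
        paste(range(table(sim$cohort$samples$form,
                          sim$cohort$samples$day)), collapse = "-"))
message("planted modules: ", max(labels),
        "; regulators: ", length(sim$truth$regulators))
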