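#!/usr/bin/env Rscript
# Expression filtering, TMM log2-CPM normalization, sample-network
# outlier detection, reproducibility correlations and variance
# partitioning.

source("analysis/00_config.R")

sim <- cohort_and_truth()
filtered <- filter_low_expressed(sim$cohort, group_by = NULL)
message("genes kept after low-expression filter: ",
        nrow(filtered$counts), " / ", nrow(sim$cohort$counts))

e <- tmm_normalize(filtered)
write_tsv(data.frame(sample_id = names(e$norm_factors),
                     norm_factor = unname(e$norm_factors),
                     lib_size = unname(e$lib_sizes)),
          "tmm_factors.tsv")

outliers <- detect_outliers(e)
message("outlying samples (z < -2 within day x form): ",
        sum(outliers$removed))
write_tsv(outliers, "outlier_report.tsv")

rep_cor <- reproducibility_correlations(e)
by_label <- aggregate(rho ~ label, rep_cor, function(x)
  c(mean = mean(x), n = length(x)))
print(by_label)
write_tsv(rep_cor, "reproducibility_correlations.tsv")

# variance partition on a subset of genes (REML per gene)
set.seed(SEED)
sub <- e
keep <- sample(nrow(e$values), 200)
sub$values <- e$values[keep, ]
vf <- variance_fractions(sub, terms = c("day", "form", "individual_id",
                                        "batch"))
message("median variance fraction by term:")
print(round(apply(vf, 2, median), 3))
write_tsv(data.frame(gene = rownames(vf), vf), "variance_fractions.tsv")
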