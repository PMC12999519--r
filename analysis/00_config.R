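# Shared settings for the analysis scripts. Every script sources this
# file, re-creates the synthetic cohort deterministically from the same
# configuration, and writes its tables under results/.

library(convorg)

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

SEED <- 20260924L

COHORT_CONFIG <- sim_config(
  n_genes = 2000,
  n_forms = 10,                        # nine disorder forms plus control
  days = c(25, 50, 75, 100),
  individuals_per_form = 3,
  convergence_schedule = c(0.1, 0.3, 0.6, 0.9),
  seed = SEED)

COVARIATES <- c("sex", "batch", "ancestry_pc1", "ancestry_pc2",
                "seq_pc1", "seq_pc2")

cohort_and_truth <- function() simulate_cohort(COHORT_CONFIG)

normalized_expression <- function(sim, regress = FALSE) {
  e <- tmm_normalize(filter_low_expressed(sim$cohort, group_by = NULL))
  if (regress) e <- regress_covariates(e, covariates = COVARIATES)
  e
}

write_tsv <- function(d, name) {
  write.table(d, file.path(RESULTS, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("wrote ", file.path(RESULTS, name))
}
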