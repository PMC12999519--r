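#!/usr/bin/env Rscript
# IP-MS connectedness: zero-imputed mean bait-prey logFC of the planted
# network against a size-matched permutation null, plus cross-list
# connectedness of external gene lists.

source("analysis/00_config.R")

ip <- simulate_ipms(n_baits = 6, universe_size = 300, clique_size = 15,
                    effect = 2, sigma = 0.5, seed = SEED)
write_ipms(ip$table, file.path(RESULTS, "ipms_table.tsv"))

obs <- connectedness(ip$table, ip$truth$members)
message("observed connectedness of the planted network: ",
        round(obs, 3))

pz <- permutation_z(ip$table, ip$truth$members, n_perm = 10000,
                    seed = SEED)
print(pz)
write_tsv(pz, "ppi_core_connectedness.tsv")

set.seed(SEED)
lists <- list(
  planted_overlap = c(sample(ip$truth$members, 8),
                      sample(setdiff(ip$table$universe,
                                     ip$truth$members), 8)),
  random = sample(setdiff(ip$table$universe, ip$truth$members), 16))
res <- cross_list_connectedness(ip$table, ip$truth$members, lists,
                                n_perm = 5000, seed = SEED)
write_tsv(res, "ppi_cross_list_connectedness.tsv")
message("cross-list z scores: ",
        paste(res$list, round(res$z, 2), sep = "=", collapse = ", "))
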