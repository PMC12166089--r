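#!/usr/bin/env Rscript
# Simulate a longitudinal host cohort, its immune measures, a latent
# multi-component gut community, and the multi-amplicon sequencing
# observation of that community.

source("analysis/00_config.R")

sim <- simulate_hosts(cfg$n_individuals, n_clans = cfg$n_clans,
                      repeat_fraction = cfg$repeat_fraction, seed = cfg$seed)
md <- simulate_immune(sim$metadata, seed = cfg$seed + 1)
md <- md[seq_len(min(cfg$n_samples, nrow(md))), ]

eff <- default_effect_config(cfg$n_taxa, beta_age = cfg$beta_age,
                             beta_iga = cfg$beta_iga,
                             beta_mucin = cfg$beta_mucin,
                             seed = cfg$seed + 2)
lat <- simulate_latent(md, sim$hosts, effect_config = eff,
                       seed = cfg$seed + 3)
des <- amplicon_design(lat$taxa, n_amplicons = cfg$n_amplicons,
                       n_asvs_per_taxon = 1, depth_mean = cfg$depth_mean,
                       seed = cfg$seed + 4)
obs <- render_amplicons(lat, des, seed = cfg$seed + 5)

write_table(sim$hosts, "hosts.csv")
write_table(md, "metadata.csv")
write_table(obs$truth, "asv_truth.csv")
write_table(obs$taxonomy, "taxonomy.csv")
for (i in seq_along(obs$tables)) {
  amp <- attr(obs$tables[[i]], "amplicon_id")
  write_matrix(obs$tables[[i]], sprintf("counts_%s.csv", amp))
}
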