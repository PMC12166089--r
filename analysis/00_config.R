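# Shared configuration for the numbered analysis drivers. Each driver can
# be run on its own (later steps recompute what they need from the tables
# under results/), in order:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_preprocess_merge.R
#   Rscript analysis/03_distance_repeatability.R
#   Rscript analysis/04_dyadic_model.R
#   Rscript analysis/05_immune_prediction.R
#   Rscript analysis/06_network.R

suppressPackageStartupMessages(library(casvpipe))

cfg <- list(
  seed            = 2024,
  n_individuals   = 110,
  n_clans         = 3,
  repeat_fraction = 0.35,
  n_samples       = 150,
  n_taxa          = 40,
  n_amplicons     = 3,
  depth_mean      = 1e4,
  beta_age        = 0.3,   # latent log-abundance slope on log age
  beta_iga        = -0.2,  # latent slope on faecal IgA
  beta_mucin      = -0.2,  # latent slope on faecal mucin
  mcmc_chains     = 4,
  mcmc_iter       = 3000,
  mcmc_warmup     = 1000,
  network_lambda  = 0.15,  # L1 penalty suited to this 40-taxon community
  results_dir     = "results"
)

dir.create(cfg$results_dir, showWarnings = FALSE, recursive = TRUE)

res_path <- function(...) file.path(cfg$results_dir, ...)

write_table <- function(df, name) {
  utils::write.csv(df, res_path(name), row.names = FALSE)
  cat(sprintf("wrote %s (%d rows)\n", res_path(name), nrow(df)))
}

read_matrix <- function(name) {
  df <- utils::read.csv(res_path(name), check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_matrix <- function(m, name) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, res_path(name), row.names = FALSE)
  cat(sprintf("wrote %s (%d x %d)\n", res_path(name), nrow(m), ncol(m)))
}
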