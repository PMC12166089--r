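#!/usr/bin/env Rscript
# Bayesian dyadic regression: which host attributes predict how similar
# two gut communities are? One row per unordered sample pair, with a
# multi-membership random effect for the two individuals involved.

source("analysis/00_config.R")

simm <- read_matrix("similarity_bray.csv")
md <- utils::read.csv(res_path("metadata.csv"), check.names = FALSE)
hosts <- utils::read.csv(res_path("hosts.csv"), check.names = FALSE)
md$date <- as.Date(md$date)

md <- with_host_covariates(md, hosts)
md <- md[md$sample_id %in% rownames(simm), ]

dyad <- build_dyadic(md, simm)
fit <- fit_dyadic(dyad, chains = cfg$mcmc_chains, iter = cfg$mcmc_iter,
                  warmup = cfg$mcmc_warmup, seed = cfg$seed + 7)
print(fit)

out <- fit$summary
rownames(out) <- NULL
write_table(out, "dyadic_posterior.csv")
write_table(data.frame(n_pairs = nrow(dyad), converged = fit$converged,
                       max_rhat = max(fit$summary$rhat, na.rm = TRUE)),
            "dyadic_fit_info.csv")
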