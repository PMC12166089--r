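# Independent oracles and fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up: sort p ascending, take
# p_(i) * m / i, then the running minimum from the largest rank down,
# capped at 1, mapped back to the input order.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Classical one-way ANOVA intraclass correlation on raw 1-D values.
classical_icc_oracle <- function(x, groups) {
  groups <- factor(groups)
  fit <- summary(stats::aov(x ~ groups))[[1]]
  msb <- fit["groups", "Mean Sq"]
  msw <- fit["Residuals", "Mean Sq"]
  n_i <- as.numeric(table(groups))
  N <- length(x)
  g <- nlevels(groups)
  n0 <- (N - sum(n_i^2) / N) / (g - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

# Small end-to-end synthetic fixture: latent community observed by
# several amplicons, preprocessed and ready for merging.
make_multiamplicon_fixture <- function(n_ind = 40, n_taxa = 20,
                                       n_amplicons = 3, n_samples = 60,
                                       depth = 1e4, seed = 42, ...) {
  sim <- simulate_hosts(n_ind, n_clans = 3, repeat_fraction = 0.35,
                        seed = seed)
  md <- simulate_immune(sim$metadata, seed = seed + 1)
  md <- md[seq_len(min(n_samples, nrow(md))), ]
  cfg <- default_effect_config(n_taxa, seed = seed + 2, ...)
  lat <- simulate_latent(md, sim$hosts, effect_config = cfg, seed = seed + 3)
  des <- amplicon_design(lat$taxa, n_amplicons = n_amplicons,
                         n_asvs_per_taxon = 1, depth_mean = depth,
                         seed = seed + 4)
  obs <- render_amplicons(lat, des, seed = seed + 5)
  list(hosts = sim$hosts, metadata = md, latent = lat, design = des,
       tables = obs$tables, truth = obs$truth, taxonomy = obs$taxonomy)
}

# A hand-built taxon_network (edge list only), for centrality checks.
make_network <- function(nodes, edges_a, edges_b) {
  structure(list(
    nodes = nodes,
    edges = data.frame(node_a = edges_a, node_b = edges_b,
                       weight = rep(1, length(edges_a)),
                       sign = rep("positive", length(edges_a)),
                       stringsAsFactors = FALSE),
    lambda = NA_real_, symmetrize = "or", dropped = character(0)),
    class = "taxon_network")
}
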