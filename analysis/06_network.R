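#!/usr/bin/env Rscript
# Sparse co-occurrence network over the merged community (CLR transform,
# Meinshausen-Buhlmann neighbourhood selection), node centralities, and a
# comparison of centrality between the immune-predictive taxa and the rest.

source("analysis/00_config.R")

casv <- read_matrix("casv_table.csv")
imp <- utils::read.csv(res_path("rf_importance.csv"), check.names = FALSE)

clr <- clr_transform(casv)
nw <- mb_network(clr, lambda = cfg$network_lambda)
cs <- centralities(nw)

# immune-predictive group: top-5 permutation-importance community features
# for either outcome (host covariates like age are not network nodes)
imp <- imp[imp$variable %in% cs$node, ]
pred <- unique(unlist(lapply(split(imp, imp$outcome), function(d)
  d$variable[order(d$rank)][1:5])))

write_table(nw$edges, "network_edges.csv")
write_table(cs, "network_centralities.csv")

if (length(pred) >= 2 && sum(!cs$node %in% pred) >= 2) {
  cmp <- compare_centrality(cs, pred)
  write_table(cmp, "centrality_comparison.csv")
  print(cmp, digits = 3)
}
cat(sprintf("network: %d nodes, %d edges (%.0f%% positive)\n",
            length(nw$nodes), nrow(nw$edges),
            if (nrow(nw$edges)) 100 * mean(nw$edges$sign == "positive")
            else 0))
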