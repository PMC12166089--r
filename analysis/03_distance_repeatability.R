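#!/usr/bin/env Rscript
# Between-sample beta-diversity of the merged community and the
# distance-based repeatability (dICC) of individual signatures, overall
# and per taxonomic component.

source("analysis/00_config.R")

casv <- read_matrix("casv_table.csv")
md <- utils::read.csv(res_path("metadata.csv"), check.names = FALSE)
taxonomy <- utils::read.csv(res_path("taxonomy.csv"), check.names = FALSE)
mapping <- utils::read.csv(res_path("casv_mapping.csv"), check.names = FALSE)

ids <- md$individual_id[match(rownames(casv), md$sample_id)]
stopifnot(!anyNA(ids))

rows <- list()
for (metric in c("bray", "jaccard", "aitchison")) {
  for (comp in c("overall", "bacteria", "fungi", "parasites")) {
    keep <- component_subset(mapping, taxonomy, comp)
    if (length(keep) < 2) next
    sub <- casv[, colnames(casv) %in% keep, drop = FALSE]
    dm <- suppressWarnings(beta_diversity(sub, metric))
    dr <- dicc(dm, ids, n_boot = 1000, seed = cfg$seed + 6)
    rows[[length(rows) + 1]] <- data.frame(
      metric = metric, component = comp, n_casvs = ncol(sub),
      dicc = dr$dicc, se = dr$se, n_individuals = dr$n_individuals)
  }
}
dicc_df <- do.call(rbind, rows)
write_table(dicc_df, "dicc.csv")
print(dicc_df, digits = 3)

# the Bray-Curtis similarity matrix feeds the dyadic model downstream
simm <- to_similarity(beta_diversity(casv, "bray"))
write_matrix(simm, "similarity_bray.csv")
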