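#!/usr/bin/env Rscript
# Filter and normalise the per-amplicon ASV tables, collate them over the
# sample union, and merge co-abundant within-genus ASVs into cASVs.

source("analysis/00_config.R")

files <- list.files(cfg$results_dir, pattern = "^counts_.*\\.csv$",
                    full.names = FALSE)
stopifnot(length(files) > 0)
tables <- lapply(files, function(f) {
  m <- read_matrix(f)
  attr(m, "amplicon_id") <- sub("^counts_(.*)\\.csv$", "\\1", f)
  m
})

taxonomy <- utils::read.csv(res_path("taxonomy.csv"), check.names = FALSE)
truth <- utils::read.csv(res_path("asv_truth.csv"), check.names = FALSE)

pp <- preprocess_amplicons(tables)
mg <- merge_casvs(pp, taxonomy)

true_taxon <- truth$taxon_id[match(mg$mapping$asv_id, truth$asv_id)]
summary_df <- data.frame(
  n_asvs_input = ncol(pp$rel_abundance),
  n_casvs = ncol(mg$casv_table),
  n_merged_groups = sum(!mg$mapping$singleton[!duplicated(mg$mapping$casv_id)]),
  recovery_ari = ari(mg$mapping$casv_id, true_taxon),
  conservation_max_error =
    max(abs(rowSums(mg$casv_table) - rowSums(pp$rel_abundance))))

write_matrix(mg$casv_table, "casv_table.csv")
write_table(mg$mapping, "casv_mapping.csv")
write_table(summary_df, "merge_summary.csv")
print(summary_df)
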