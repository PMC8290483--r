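#!/usr/bin/env Rscript
# Stage 6 -- genus-level differential abundance, week-1 vs week-4 mothers.
#
# Aggregates the cleaned bacterial table to genus-level labels, tests each
# genus's relative abundance between the two maternal groups with rank-sum
# tests under Benjamini-Hochberg correction, and reports the most abundant
# genera overall.

suppressPackageStartupMessages(library(biomepipe))

SEED <- 101L
if (!file.exists("results/cleaned_16s.tsv")) {
  stop("run analysis/02_decontam.R first", call. = FALSE)
}
study <- read_study("results/sim_study")
cfg <- analysis_config(rng_seed = SEED)

cleaned <- read_count_table("results/cleaned_16s.tsv")
tax <- study$taxonomy[study$taxonomy$otu_id %in% cleaned$otu_ids, ]
gt <- aggregate_by_genus(cleaned, tax)

meta <- study$metadata[study$metadata$domain == "bacteria_16S" &
                         study$metadata$sample_id %in% gt$sample_ids, ]
wk1 <- meta$sample_id[meta$age_bin == "Mother-wk1"]
wk4 <- meta$sample_id[meta$age_bin == "Mother-wk4"]
ra <- relative_abundance(subset_count_table(gt, c(wk1, wk4)))
res <- group_difference_test(ra, wk1, wk4, alpha_level = cfg$alpha_level)
write_report(res, "results/diffabund_mothers.tsv", params = cfg,
             seed = SEED)

cat("Genus-level test, week-1 (n = ", length(wk1), ") vs week-4 (n = ",
    length(wk4), ") mothers: ", sum(res$significant), "/", nrow(res),
    " genera differ (BH-adjusted p < ", cfg$alpha_level, ")\n", sep = "")
sig <- res[res$significant, ]
for (i in seq_len(nrow(sig))) {
  cat(sprintf("  %-22s %s in week-1 (adj p = %.2g)\n", sig$label[i],
              if (sig$direction[i] > 0) "higher" else "lower",
              sig$adjusted_p[i]))
}

ra_all <- relative_abundance(
  subset_count_table(gt, meta$sample_id[meta$sample_type %in%
                                          c("child_stool", "mother_stool")]))
top <- top_genera(ra_all, 25)
write_report(data.frame(rank = seq_along(top), genus = top,
                        mean_relabund = rowMeans(ra_all)[top],
                        stringsAsFactors = FALSE),
             "results/top_genera_16s.tsv", params = cfg, seed = SEED)
cat("\nTop genera and the maternal test table are in results/\n")
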