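#!/usr/bin/env Rscript
# Stage 3 -- rarefaction-based alpha diversity vs the adult reference.
#
# Rarefies each domain's cleaned stool table to the minimum retained depth,
# computes observed richness and Shannon diversity per sample, and compares
# every age bin to the week-4 mothers (the adult reference) with two-sided
# rank-sum tests under Bonferroni correction.

suppressPackageStartupMessages(library(biomepipe))

SEED <- 101L
if (!file.exists("results/cleaned_16s.tsv")) {
  stop("run analysis/02_decontam.R first", call. = FALSE)
}
study <- read_study("results/sim_study")
cfg <- analysis_config(rng_seed = SEED)

for (domain in c("bacteria_16S", "fungi_ITS2")) {
  tag <- if (domain == "bacteria_16S") "16s" else "its2"
  cleaned <- read_count_table(file.path("results",
                                        paste0("cleaned_", tag, ".tsv")))
  meta <- study$metadata[study$metadata$domain == domain &
                           study$metadata$sample_id %in% cleaned$sample_ids &
                           study$metadata$sample_type %in%
                           c("child_stool", "mother_stool"), ]
  a <- alpha_diversity(subset_count_table(cleaned, meta$sample_id),
                       seed = SEED)
  write_report(a, file.path("results", paste0("alpha_", tag, ".tsv")),
               params = cfg, seed = SEED)
  cat("\n[", domain, "] rarefied ", nrow(a), " stool samples to depth ",
      a$rarefaction_depth[1], "\n", sep = "")
  for (metric in c("shannon", "richness")) {
    cmp <- suppressWarnings(
      compare_bins_to_reference(a, meta, "Mother-wk4", metric = metric,
                                alpha_level = cfg$alpha_level))
    write_report(cmp, file.path("results",
                                paste0("alpha_bins_", tag, "_", metric,
                                       ".tsv")),
                 params = cfg, seed = SEED)
    below <- cmp$age_bin[cmp$significant & cmp$direction < 0]
    cat("  ", metric, ": ", sum(cmp$significant), "/", nrow(cmp),
        " bins differ from the adult reference",
        if (length(below)) paste0(" (below: ",
                                  paste(below, collapse = ", "), ")"),
        "\n", sep = "")
  }
}
cat("\nPer-sample alpha tables and bin tests are in results/\n")
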