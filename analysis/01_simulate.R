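#!/usr/bin/env Rscript

# Stage 1 -- simulate the study cohort.
#
# Generates the synthetic longitudinal two-arm community at study scale:
# 150 genera, 30 samples per group per timepoint across three samplings,
# four planted co-occurrence modules and eight driver genera whose mean
# abundance shifts (log2 FC 1.5) and whose correlation structure rewires in
# the stress arm. Writes the three data tables plus the planted ground truth.

suppressPackageStartupMessages(library(netshiftr))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

cfg <- simulation_config(seed = derive_seed(seed, "simulate"))
sim <- simulate_counts(cfg)

write_count_table(sim$table, file.path(out_dir, "counts.tsv"))
write.table(sim$metadata, file.path(out_dir, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$table$taxonomy, file.path(out_dir, "taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(drivers = sim$truth$drivers,
       module_assignment_control = as.list(sim$truth$module_assignment$control),
       module_assignment_stress = as.list(sim$truth$module_assignment$stress)),
  file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)

message(sprintf("simulated %d samples x %d genera over %d timepoints (%s)",
                nrow(sim$table$counts), ncol(sim$table$counts),
                nlevels(sim$metadata$timepoint),
                paste(levels(sim$metadata$timepoint), collapse = ", ")))
message(sprintf("planted drivers: %s", paste(sim$truth$drivers, collapse = ", ")))
message("wrote counts.tsv, metadata.tsv, taxonomy.tsv, ground_truth.json to ", out_dir)
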