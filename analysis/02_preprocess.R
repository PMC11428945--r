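#!/usr/bin/env Rscript

# Stage 2 -- count-level filters and rarefaction.
#
# Removes singleton taxa, drops taxa at or below 0.0001% of the pooled read
# total (strict threshold), then rarefies every sample to 31,731 reads
# without replacement, dropping samples below that depth.

suppressPackageStartupMessages(library(netshiftr))

data_dir <- "results/data"
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

tbl <- read_count_table(file.path(data_dir, "counts.tsv"),
                        taxonomy = read_taxonomy(file.path(data_dir, "taxonomy.tsv")))
st1 <- remove_singletons(tbl)
st2 <- filter_low_abundance(st1$table, fraction = 1e-6)
st3 <- rarefy(st2$table, depth = 31731L, seed = derive_seed(seed, "rarefy"))

report <- list(order = c("remove_singletons", "filter_low_abundance", "rarefy"),
               n_taxa_in = st1$report$n_taxa_in,
               n_removed_singletons = st1$report$n_removed_singletons,
               n_removed_low_abundance = st2$report$n_removed_low_abundance,
               n_samples_dropped = st3$report$n_samples_dropped,
               rarefaction_depth = st3$report$rarefaction_depth)
jsonlite::write_json(report, file.path(out_dir, "filter_report.json"),
                     auto_unbox = TRUE)
write_count_table(st3$table, file.path(out_dir, "counts_rarefied.tsv"))

message(sprintf("filters: %d taxa in, %d singletons removed, %d below 0.0001%%, %d samples under depth",
                report$n_taxa_in, report$n_removed_singletons,
                report$n_removed_low_abundance, report$n_samples_dropped))
message(sprintf("every surviving sample now totals exactly %d reads (%d samples x %d taxa)",
                report$rarefaction_depth, nrow(st3$table$counts),
                ncol(st3$table$counts)))
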