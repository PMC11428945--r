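#!/usr/bin/env Rscript

# Stage 4 -- co-occurrence networks per condition.
#
# Infers a SparCC network for each condition at each timepoint (six
# networks), integrates them into one network per condition with
# inverse-variance (Fisher-z) weights, and compares node-level topology
# between the integrated control and stress networks.

suppressPackageStartupMessages(library(netshiftr))

out_dir <- "results/analysis"
seed <- 1L

tbl <- read_count_table(file.path(out_dir, "counts_rarefied.tsv"))
md <- read_metadata("results/data/metadata.tsv")
md <- md[md$sample_id %in% rownames(tbl$counts), ]
al <- align_samples(tbl, md)

ctrl <- nmss_control()
nets <- lapply(stats::setNames(c("control", "stress"), c("control", "stress")),
               function(g) {
  per_tp <- lapply(levels(al$metadata$timepoint), function(tp) {
    ids <- al$metadata$sample_id[al$metadata$group == g &
                                   al$metadata$timepoint == tp]
    sparcc(count_table(al$table$counts[ids, , drop = FALSE]),
           seed = derive_seed(seed, paste0("net_", g, "_", tp)),
           condition = g)
  })
  integrate_networks(per_tp)
})

topo <- lapply(nets, topology)
cmp <- compare_topology(topo$control, topo$stress)
write_result(cmp, file.path(out_dir, "topology_comparison.tsv"))
for (g in names(nets)) {
  write_edge_list(nets[[g]], file.path(out_dir, paste0("network_", g, "_edges.tsv")))
  write_result(topo[[g]]$nodes, file.path(out_dir, paste0("topology_", g, ".tsv")))
}

deg <- cmp[cmp$metric == "degree", ]
message(sprintf("mean node degree: control %.2f vs stress %.2f (Mann-Whitney p = %.3g)",
                deg$mean_a, deg$mean_b, deg$p_value))
message(sprintf("edges above |r| >= %.2f: control %d, stress %d",
                topo$control$edge_threshold,
                topo$control$summary$n_edges, topo$stress$summary$n_edges))
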