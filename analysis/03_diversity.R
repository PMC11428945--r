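#!/usr/bin/env Rscript

# Stage 3 -- diversity statistics.
#
# Per-sample alpha diversity (Shannon, Simpson, Chao1, ACE), Bray-Curtis
# distances with a PCoA ordination, Whittaker beta diversity per group and
# timepoint, and a PERMANOVA for the effect of sex on community structure.

suppressPackageStartupMessages(library(netshiftr))

out_dir <- "results/analysis"
seed <- 1L

tbl <- read_count_table(file.path(out_dir, "counts_rarefied.tsv"))
md <- read_metadata("results/data/metadata.tsv")
md <- md[md$sample_id %in% rownames(tbl$counts), ]
al <- align_samples(tbl, md)

alpha <- alpha_suite(al$table)
write_result(alpha, file.path(out_dir, "alpha_diversity.tsv"))

bc <- bray_curtis(al$table)
write.table(round(bc, 6), file.path(out_dir, "bray_curtis.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
ord <- pcoa_ordination(bc, n_axes = 2L)
write_result(data.frame(sample_id = rownames(ord$coordinates),
                        ord$coordinates),
             file.path(out_dir, "pcoa.tsv"))

groups <- expand.grid(group = levels(al$metadata$group),
                      timepoint = levels(al$metadata$timepoint),
                      stringsAsFactors = FALSE)
groups$whittaker <- vapply(seq_len(nrow(groups)), function(i) {
  ids <- al$metadata$sample_id[al$metadata$group == groups$group[i] &
                                 al$metadata$timepoint == groups$timepoint[i]]
  whittaker_beta(al$table, ids)
}, numeric(1))
write_result(groups, file.path(out_dir, "whittaker_beta.tsv"))

perm <- permanova(bc, al$metadata$sex, n_permutations = 999L,
                  seed = derive_seed(seed, "diversity"))
jsonlite::write_json(perm, file.path(out_dir, "permanova_sex.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("alpha: mean Shannon %.3f (range %.3f-%.3f) over %d samples",
                mean(alpha$shannon), min(alpha$shannon), max(alpha$shannon),
                nrow(alpha)))
message(sprintf("PCoA axis 1 explains %.1f%% of Bray-Curtis variance",
                100 * ord$proportion_explained[1]))
message(sprintf("PERMANOVA for sex: pseudo-F %.2f, R2 %.3f, p = %.3f %s",
                perm$pseudo_F, perm$R2, perm$p_value,
                if (perm$p_value > 0.05) "(sex plays a minor role)" else ""))
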