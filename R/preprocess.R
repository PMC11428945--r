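new_filter_report <- function(n_taxa_in,
                              n_removed_singletons = 0L,
                              n_removed_low_abundance = 0L,
                              n_samples_dropped = 0L,
                              rarefaction_depth = NA_integer_) {
  list(n_taxa_in = as.integer(n_taxa_in),
       n_removed_singletons = as.integer(n_removed_singletons),
       n_removed_low_abundance = as.integer(n_removed_low_abundance),
       n_samples_dropped = as.integer(n_samples_dropped),
       rarefaction_depth = rarefaction_depth)
}

#' Remove singleton taxa
#'
#' A singleton is a taxon whose total count across all samples equals 1.
#'
#' @param table a [count_table].
#' @return list(table, report); `report$n_removed_singletons` counts the
#'   removals. An empty result is allowed and flagged by a warning.
#' @export
remove_singletons <- function(table) {
  totals <- colSums(table$counts)
  keep <- totals != 1
  if (!any(keep)) warning("all taxa were singletons; result is empty")
  out <- subset_taxa(table, keep)
  list(table = out,
       report = new_filter_report(ncol(table$counts),
                                  n_removed_singletons = sum(!keep)))
}

#' Filter taxa below a fraction of the pooled total abundance
#'
#' A taxon is retained iff its total count, as a fraction of the grand total
#' over all samples and taxa (computed before any removal), is strictly
#' greater than `fraction`. The default 1e-6 corresponds to 0.0001% of the
#' total abundance.
#'
#' @param table a [count_table].
#' @param fraction threshold in \[0, 1).
#' @return list(table, report).
#' @export
filter_low_abundance <- function(table, fraction = 1e-6) {
  stopifnot(fraction >= 0, fraction < 1)
  totals <- colSums(table$counts)
  grand <- sum(totals)
  if (grand == 0) stop_user("empty count table")
  keep <- totals / grand > fraction
  list(table = subset_taxa(table, keep),
       report = new_filter_report(ncol(table$counts),
                                  n_removed_low_abundance = sum(!keep)))
}

subset_taxa <- function(table, keep) {
  counts <- table$counts[, keep, drop = FALSE]
  tx <- table$taxonomy
  if (!is.null(tx)) tx <- tx[tx$taxon_id %in% colnames(counts), , drop = FALSE]
  count_table(counts, taxonomy = tx)
}

#' Rarefy samples to a common depth
#'
#' Each sample with total >= `depth` is replaced by a uniform subsample
#' without replacement (multivariate hypergeometric, via
#' [vegan::rrarefy()]) of exactly `depth` reads; samples below depth are
#' dropped and counted in the report.
#'
#' @param table a [count_table].
#' @param depth target depth (default 31731 reads).
#' @param seed integer seed for reproducible subsampling.
#' @return list(table, report).
#' @export
rarefy <- function(table, depth = 31731L, seed = NULL) {
  stopifnot(depth >= 1)
  totals <- rowSums(table$counts)
  survive <- totals >= depth
  if (!any(survive)) stop_user("no samples survive rarefaction at depth ", depth)
  m <- table$counts[survive, , drop = FALSE]
  out <- with_seed(seed, {
    r <- m
    needs <- rowSums(m) > depth
    if (any(needs)) {
      # suppress vegan's raw-counts heuristic warning; these are raw counts
      r[needs, ] <- suppressWarnings(
        vegan::rrarefy(m[needs, , drop = FALSE], depth))
    }
    r
  })
  tbl <- count_table(out, taxonomy = table$taxonomy)
  list(table = tbl,
       report = new_filter_report(ncol(table$counts),
                                  n_samples_dropped = sum(!survive),
                                  rarefaction_depth = as.integer(depth)))
}

#' Aggregate counts to a taxonomic rank
#'
#' Counts are summed over taxa sharing the lineage down to `rank`. Taxa with
#' no classification at `rank` are grouped under their lowest classified
#' level with an `unclassified_` prefix. Per-sample totals are conserved
#' exactly.
#'
#' @param table a [count_table] with taxonomy.
#' @param rank one of the taxonomy's rank columns (e.g. "Genus").
#' @return A [count_table] keyed by aggregated taxa.
#' @export
aggregate_to_rank <- function(table, rank = "Genus") {
  tx <- table$taxonomy
  if (is.null(tx)) stop_user("aggregate_to_rank requires taxonomy")
  ranks <- setdiff(names(tx), "taxon_id")
  if (!rank %in% ranks) stop_user("rank '", rank, "' not in taxonomy columns")
  missing <- setdiff(colnames(table$counts), tx$taxon_id)
  if (length(missing)) stop_user("taxonomy missing for: ",
                                 paste(utils::head(missing, 5), collapse = ", "))
  tx <- tx[match(colnames(table$counts), tx$taxon_id), , drop = FALSE]
  upto <- seq_len(match(rank, ranks))
  key <- vapply(seq_len(nrow(tx)), function(i) {
    lineage <- as.character(tx[i, ranks[upto], drop = TRUE])
    lineage[is.na(lineage) | lineage == ""] <- NA_character_
    if (is.na(lineage[length(lineage)])) {
      classified <- which(!is.na(lineage))
      if (!length(classified)) return("unclassified_root")
      paste0("unclassified_", lineage[max(classified)])
    } else {
      lineage[length(lineage)]
    }
  }, character(1))
  agg <- t(rowsum(t(table$counts), group = key))
  count_table(agg)
}

#' Convert counts to relative abundances
#'
#' @param table a [count_table].
#' @return A numeric matrix whose rows each sum to 1.
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    stop_user("all-zero sample(s): ",
              paste(rownames(table$counts)[totals == 0], collapse = ", "))
  }
  table$counts / totals
}
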