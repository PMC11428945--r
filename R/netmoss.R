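#' Control parameters for the network-shift pipeline
#'
#' Bundles the SparCC, module-detection and scoring parameters shared by
#' [nmss_significance], [run_per_timepoint] and [run_longitudinal].
#' `permutation_inner_iterations` is the reduced SparCC iteration count
#' used inside permutation nulls (economy mode, recorded in output).
#'
#' @param n_inner_iterations SparCC Dirichlet iterations for observed
#'   networks (default 20).
#' @param exclusion_threshold,n_exclusion_rounds,pseudocount SparCC
#'   parameters (see [sparcc]).
#' @param edge_threshold |correlation| threshold defining graph edges
#'   (default 0.3), shared with [topology].
#' @param soft_power,min_module_size,cut_height module detection parameters
#'   (see [detect_modules]).
#' @param stability_threshold Jaccard distance below which a module pair is
#'   flagged stable (default 0.3).
#' @param permutation_inner_iterations SparCC iterations inside permutation
#'   nulls (default 5).
#' @return A named list of class `nmss_control`.
#' @export
nmss_control <- function(n_inner_iterations = 20L, exclusion_threshold = 0.1,
                         n_exclusion_rounds = 10L, pseudocount = 0.5,
                         edge_threshold = 0.3, soft_power = 6L,
                         min_module_size = 5L, cut_height = 0.9,
                         stability_threshold = 0.3,
                         permutation_inner_iterations = 5L) {
  structure(list(n_inner_iterations = n_inner_iterations,
                 exclusion_threshold = exclusion_threshold,
                 n_exclusion_rounds = n_exclusion_rounds,
                 pseudocount = pseudocount,
                 edge_threshold = edge_threshold,
                 soft_power = soft_power,
                 min_module_size = min_module_size,
                 cut_height = cut_height,
                 stability_threshold = stability_threshold,
                 permutation_inner_iterations = permutation_inner_iterations),
            class = "nmss_control")
}

#' Differential module distance between two condition networks
#'
#' The module-pair distance matrix D holds the Jaccard distance
#' \eqn{1 - |M_A \cap M_B| / |M_A \cup M_B|} between every module of
#' network A and every module of network B (member sets over the shared
#' taxon universe; unassigned nodes form the pseudo-module "grey").
#' Module pairs with distance below `stability_threshold` are flagged as
#' stable ("intersection") modules. Per node, the sets of modules housing
#' its supra-threshold graph neighbors in A and in B are recorded
#' (`neighbors_A`, `neighbors_B`), along with the node-pair co-membership
#' structures consumed by [nmss].
#'
#' @param net_a,net_b [correlation_network]s on a shared taxon universe.
#' @param part_a,part_b `module_partition`s of the two networks.
#' @param edge_threshold |correlation| threshold for graph adjacency
#'   (default 0.3).
#' @param stability_threshold Jaccard stability flag threshold
#'   (default 0.3).
#' @return An object of class `differential_module_distance`.
#' @export
differential_module_distance <- function(net_a, part_a, net_b, part_b,
                                         edge_threshold = 0.3,
                                         stability_threshold = 0.3) {
  if (!length(part_a$modules) || !length(part_b$modules)) {
    stop_user("empty module partition")
  }
  shared <- intersect(net_a$taxon_ids, net_b$taxon_ids)
  if (!length(shared)) stop_user("networks share no taxa")
  mod_a <- part_a$modules[shared]
  mod_b <- part_b$modules[shared]
  if (anyNA(mod_a) || anyNA(mod_b)) stop_user("partition does not cover the shared taxa")
  labs_a <- sort(unique(mod_a))
  labs_b <- sort(unique(mod_b))
  D <- matrix(NA_real_, length(labs_a), length(labs_b),
              dimnames = list(labs_a, labs_b))
  for (i in seq_along(labs_a)) {
    set_a <- shared[mod_a == labs_a[i]]
    for (j in seq_along(labs_b)) {
      set_b <- shared[mod_b == labs_b[j]]
      D[i, j] <- 1 - length(intersect(set_a, set_b)) / length(union(set_a, set_b))
    }
  }
  wa <- abs(net_a$adjacency[shared, shared])
  wb <- abs(net_b$adjacency[shared, shared])
  adj_a <- wa >= edge_threshold
  adj_b <- wb >= edge_threshold
  diag(adj_a) <- diag(adj_b) <- FALSE
  weight_a <- wa * adj_a
  weight_b <- wb * adj_b
  neighbors_A <- lapply(seq_along(shared),
                        function(i) sort(unique(mod_a[adj_a[i, ]])))
  neighbors_B <- lapply(seq_along(shared),
                        function(i) sort(unique(mod_b[adj_b[i, ]])))
  names(neighbors_A) <- names(neighbors_B) <- shared
  stable <- which(D < stability_threshold, arr.ind = TRUE)
  stable_pairs <- data.frame(module_a = labs_a[stable[, 1]],
                             module_b = labs_b[stable[, 2]],
                             distance = D[stable],
                             stringsAsFactors = FALSE)
  structure(list(D = D, taxa = shared,
                 module_a = mod_a, module_b = mod_b,
                 adjacency_a = adj_a, adjacency_b = adj_b,
                 weight_a = weight_a, weight_b = weight_b,
                 neighbors_A = neighbors_A, neighbors_B = neighbors_B,
                 stable_pairs = stable_pairs,
                 union_taxa = union(net_a$taxon_ids, net_b$taxon_ids),
                 edge_threshold = edge_threshold,
                 stability_threshold = stability_threshold),
            class = "differential_module_distance")
}

#' Network module-shift driving-force score
#'
#' For each taxon i, the raw score is the difference of two neighbor sums
#' of differential module-membership distances:
#' \deqn{raw(i) = \sum_{j \in N_A(i)} \Delta D_{ij} -
#'               \sum_{l \in N_B(i)} \Delta D_{il}}
#' where \eqn{N_X(i)} are i's supra-threshold graph neighbors in network X,
#' \eqn{\Delta D_{ij}} is the distance between the modules housing the
#' pair (i, j) in A minus that distance in B (for two modules of one
#' partition the Jaccard distance reduces to the 0/1 different-module
#' indicator), and each term is weighted by the edge strength
#' \eqn{|a_{ij}|} in the corresponding network. Taxa that changed their
#' module neighborhood between conditions accumulate large |raw|; the
#' reported score is |raw| min-max normalized to \[0, 1\]. Identical
#' networks give a score of exactly 0 for every node.
#'
#' @param dist a [differential_module_distance].
#' @param node optional single taxon ID; if given, its normalized score is
#'   returned as a scalar (NA when the node is absent from either network).
#' @return data.frame(taxon, raw, nmss) over the union taxon universe
#'   (nodes missing from a network get NA), or a scalar when `node` is
#'   given.
#' @export
nmss <- function(dist, node = NULL) {
  stopifnot(inherits(dist, "differential_module_distance"))
  diff_a <- outer(dist$module_a, dist$module_a, `!=`) * 1
  diff_b <- outer(dist$module_b, dist$module_b, `!=`) * 1
  delta <- diff_a - diff_b
  raw <- rowSums(dist$weight_a * delta) - rowSums(dist$weight_b * delta)
  score <- abs(raw)
  rng <- range(score)
  norm <- if (diff(rng) > 0) (score - rng[1]) / diff(rng) else rep(0, length(score))
  out <- data.frame(taxon = dist$union_taxa,
                    raw = NA_real_, nmss = NA_real_,
                    stringsAsFactors = FALSE)
  idx <- match(dist$taxa, dist$union_taxa)
  out$raw[idx] <- raw
  out$nmss[idx] <- norm
  if (!is.null(node)) {
    if (!node %in% out$taxon) stop_user("unknown node: ", node)
    return(out$nmss[out$taxon == node])
  }
  out
}

# Full single-contrast chain: two count tables -> networks -> partitions ->
# differential module distance -> scores.
nmss_chain <- function(table_a, table_b, control = nmss_control(),
                       seed = NULL, n_inner = NULL) {
  n_it <- n_inner %||% control$n_inner_iterations
  net_a <- sparcc(table_a, n_inner_iterations = n_it,
                  exclusion_threshold = control$exclusion_threshold,
                  n_exclusion_rounds = control$n_exclusion_rounds,
                  pseudocount = control$pseudocount,
                  seed = if (is.null(seed)) NULL else seed,
                  condition = "control")
  net_b <- sparcc(table_b, n_inner_iterations = n_it,
                  exclusion_threshold = control$exclusion_threshold,
                  n_exclusion_rounds = control$n_exclusion_rounds,
                  pseudocount = control$pseudocount,
                  seed = if (is.null(seed)) NULL else seed + 1L,
                  condition = "stress")
  part_a <- detect_modules(net_a, soft_power = control$soft_power,
                           min_module_size = control$min_module_size,
                           cut_height = control$cut_height)
  part_b <- detect_modules(net_b, soft_power = control$soft_power,
                           min_module_size = control$min_module_size,
                           cut_height = control$cut_height)
  dmd <- differential_module_distance(net_a, part_a, net_b, part_b,
                                      edge_threshold = control$edge_threshold,
                                      stability_threshold = control$stability_threshold)
  list(net_a = net_a, net_b = net_b, part_a = part_a, part_b = part_b,
       dmd = dmd, scores = nmss(dmd))
}

shared_taxa_tables <- function(table_a, table_b) {
  taxa <- intersect(colnames(table_a$counts), colnames(table_b$counts))
  if (length(taxa) < 4) stop_user("tables share fewer than 4 taxa")
  list(a = count_table(table_a$counts[, taxa, drop = FALSE]),
       b = count_table(table_b$counts[, taxa, drop = FALSE]))
}

#' Permutation significance and FDR for module-shift scores
#'
#' The null distribution is built by permuting condition labels over the
#' pooled samples and recomputing the entire chain (SparCC networks,
#' module partitions, scores) per permutation, with reduced SparCC inner
#' iterations for tractability (economy mode, recorded in the result).
#' Per-taxon \eqn{p = (1 + \#\{null \ge obs\}) / (1 + P)} (never exactly
#' 0); q-values via Benjamini-Hochberg; direction from the sign of the
#' mean relative-abundance difference between arms.
#'
#' @param scores observed score data.frame from [nmss] (or the `scores`
#'   element of a chain); if `NULL` it is computed from the tables.
#' @param table_a,table_b [count_table]s for the two conditions (samples
#'   in rows; shared taxa are used).
#' @param n_permutations at least 100 (default 1000).
#' @param seed integer seed.
#' @param control an [nmss_control].
#' @return data.frame(taxon, raw, nmss, p_value, q_value, direction) with
#'   attributes recording the permutation settings.
#' @export
nmss_significance <- function(scores = NULL, table_a, table_b,
                              n_permutations = 1000L, seed = NULL,
                              control = nmss_control()) {
  if (n_permutations < 100L) stop_user("need at least 100 permutations")
  tt <- shared_taxa_tables(table_a, table_b)
  n_a <- nrow(tt$a$counts)
  n_b <- nrow(tt$b$counts)
  if (n_a < 4 || n_b < 4) stop_user("too few samples per arm to permute into two arms")
  with_seed(seed, {
    if (is.null(scores)) {
      scores <- nmss_chain(tt$a, tt$b, control = control)$scores
    }
    taxa <- intersect(scores$taxon, colnames(tt$a$counts))
    obs <- abs(scores$raw[match(taxa, scores$taxon)])  # permutation statistic: |raw|
    pooled <- rbind(tt$a$counts, tt$b$counts)
    exceed <- rep(0L, length(taxa))
    valid <- rep(0L, length(taxa))
    for (p in seq_len(n_permutations)) {
      idx <- sample.int(n_a + n_b)
      pa <- count_table(pooled[idx[seq_len(n_a)], , drop = FALSE])
      pb <- count_table(pooled[idx[n_a + seq_len(n_b)], , drop = FALSE])
      null_scores <- nmss_chain(pa, pb, control = control,
                                n_inner = control$permutation_inner_iterations)$scores
      ns <- abs(null_scores$raw[match(taxa, null_scores$taxon)])
      ok <- !is.na(ns) & !is.na(obs)
      exceed[ok] <- exceed[ok] + (ns[ok] >= obs[ok])
      valid <- valid + ok
    }
    p_value <- (1 + exceed) / (1 + valid)
    p_value[is.na(obs)] <- NA_real_
    q_value <- stats::p.adjust(p_value, method = "BH")
    rel_a <- colMeans(tt$a$counts / rowSums(tt$a$counts))[taxa]
    rel_b <- colMeans(tt$b$counts / rowSums(tt$b$counts))[taxa]
    d <- rel_a - rel_b
    direction <- ifelse(d > 0, "enriched_in_A",
                        ifelse(d < 0, "enriched_in_B", "none"))
    out <- data.frame(taxon = taxa,
                      raw = scores$raw[match(taxa, scores$taxon)],
                      nmss = scores$nmss[match(taxa, scores$taxon)],
                      p_value = p_value, q_value = q_value,
                      direction = direction, stringsAsFactors = FALSE)
    attr(out, "n_permutations") <- as.integer(n_permutations)
    attr(out, "permutation_inner_iterations") <- control$permutation_inner_iterations
    out
  })
}

split_by_group <- function(table, metadata) {
  al <- align_samples(table, metadata)
  lapply(stats::setNames(levels(al$metadata$group), levels(al$metadata$group)),
         function(g) {
           ids <- al$metadata$sample_id[al$metadata$group == g]
           if (!length(ids)) return(NULL)
           count_table(al$table$counts[ids, , drop = FALSE],
                       taxonomy = al$table$taxonomy)
         })
}

#' Per-timepoint network-shift biomarker runs
#'
#' Runs the full chain (SparCC networks per condition, module detection,
#' module-shift scores, permutation significance) independently within
#' each sampling timepoint. Timepoints missing a condition are skipped
#' with a warning.
#'
#' @param table a [count_table] covering all timepoints.
#' @param metadata aligned metadata with `group` and `timepoint`.
#' @param n_permutations permutations for significance (default 1000).
#' @param seed integer seed (fanned out per timepoint).
#' @param control an [nmss_control].
#' @return Named list (one element per processed timepoint) of biomarker
#'   data.frames as from [nmss_significance], each with `mode` and
#'   `timepoint` columns added.
#' @export
run_per_timepoint <- function(table, metadata, n_permutations = 1000L,
                              seed = NULL, control = nmss_control()) {
  al <- align_samples(table, metadata)
  tps <- levels(al$metadata$timepoint)
  out <- list()
  for (tp in tps) {
    ids <- al$metadata$sample_id[al$metadata$timepoint == tp]
    md_tp <- al$metadata[al$metadata$timepoint == tp, , drop = FALSE]
    if (length(unique(md_tp$group)) < 2) {
      warning("timepoint ", tp, " lacks one condition; skipped")
      next
    }
    tbl_tp <- count_table(al$table$counts[ids, , drop = FALSE],
                          taxonomy = al$table$taxonomy)
    arms <- split_by_group(tbl_tp, md_tp)
    res <- nmss_significance(NULL, arms$control, arms$stress,
                             n_permutations = n_permutations,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, tp),
                             control = control)
    res$mode <- "per_timepoint"
    res$timepoint <- tp
    out[[tp]] <- res
  }
  if (!length(out)) stop_user("no timepoint has both conditions")
  out
}

longitudinal_networks <- function(arm_tables_by_tp, condition, control, n_inner, seed) {
  nets <- vector("list", length(arm_tables_by_tp))
  for (k in seq_along(arm_tables_by_tp)) {
    nets[[k]] <- sparcc(arm_tables_by_tp[[k]], n_inner_iterations = n_inner,
                        exclusion_threshold = control$exclusion_threshold,
                        n_exclusion_rounds = control$n_exclusion_rounds,
                        pseudocount = control$pseudocount,
                        seed = if (is.null(seed)) NULL else seed + k,
                        condition = condition)
  }
  integrate_networks(nets)
}

longitudinal_chain <- function(table, metadata, control, n_inner, seed) {
  al <- align_samples(table, metadata)
  tps <- levels(al$metadata$timepoint)
  arm_tabs <- function(g) {
    lapply(tps, function(tp) {
      ids <- al$metadata$sample_id[al$metadata$timepoint == tp & al$metadata$group == g]
      count_table(al$table$counts[ids, , drop = FALSE])
    })
  }
  net_a <- longitudinal_networks(arm_tabs("control"), "control", control, n_inner,
                                 if (is.null(seed)) NULL else seed)
  net_b <- longitudinal_networks(arm_tabs("stress"), "stress", control, n_inner,
                                 if (is.null(seed)) NULL else seed + 1000L)
  part_a <- detect_modules(net_a, soft_power = control$soft_power,
                           min_module_size = control$min_module_size,
                           cut_height = control$cut_height)
  part_b <- detect_modules(net_b, soft_power = control$soft_power,
                           min_module_size = control$min_module_size,
                           cut_height = control$cut_height)
  dmd <- differential_module_distance(net_a, part_a, net_b, part_b,
                                      edge_threshold = control$edge_threshold,
                                      stability_threshold = control$stability_threshold)
  list(net_a = net_a, net_b = net_b, part_a = part_a, part_b = part_b,
       dmd = dmd, scores = nmss(dmd))
}

#' Longitudinal (integrated, "multiple files" style) biomarker run
#'
#' Per condition, SparCC networks are inferred at every timepoint and
#' integrated via [integrate_networks]; module detection, module-shift
#' scoring and permutation significance then operate on the two integrated
#' networks. Permutations shuffle condition labels within each timepoint
#' stratum and recompute the whole construction.
#'
#' @inheritParams run_per_timepoint
#' @return A biomarker data.frame as from [nmss_significance], with
#'   `mode = "longitudinal"`, plus the fitted networks in attributes.
#' @export
run_longitudinal <- function(table, metadata, n_permutations = 1000L,
                             seed = NULL, control = nmss_control()) {
  if (n_permutations < 100L) stop_user("need at least 100 permutations")
  al <- align_samples(table, metadata)
  if (nlevels(droplevels(al$metadata$timepoint)) < 2) {
    stop_user("longitudinal mode needs >= 2 timepoints")
  }
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "longitudinal"), {
    chain <- longitudinal_chain(al$table, al$metadata, control,
                                control$n_inner_iterations, seed = NULL)
    taxa <- chain$dmd$taxa
    obs <- abs(chain$scores$raw[match(taxa, chain$scores$taxon)])
    exceed <- rep(0L, length(taxa))
    valid <- rep(0L, length(taxa))
    md <- al$metadata
    for (p in seq_len(n_permutations)) {
      md_perm <- md
      for (tp in levels(md$timepoint)) {
        idx <- which(md$timepoint == tp)
        md_perm$group[idx] <- md$group[idx][sample.int(length(idx))]
      }
      null_chain <- longitudinal_chain(al$table, md_perm, control,
                                       control$permutation_inner_iterations,
                                       seed = NULL)
      ns <- abs(null_chain$scores$raw[match(taxa, null_chain$scores$taxon)])
      ok <- !is.na(ns) & !is.na(obs)
      exceed[ok] <- exceed[ok] + (ns[ok] >= obs[ok])
      valid <- valid + ok
    }
    p_value <- (1 + exceed) / (1 + valid)
    q_value <- stats::p.adjust(p_value, method = "BH")
    arms <- split_by_group(al$table, al$metadata)
    rel_a <- colMeans(arms$control$counts / rowSums(arms$control$counts))[taxa]
    rel_b <- colMeans(arms$stress$counts / rowSums(arms$stress$counts))[taxa]
    d <- rel_a - rel_b
    out <- data.frame(taxon = taxa,
                      raw = chain$scores$raw[match(taxa, chain$scores$taxon)],
                      nmss = chain$scores$nmss[match(taxa, chain$scores$taxon)],
                      p_value = p_value, q_value = q_value,
                      direction = ifelse(d > 0, "enriched_in_A",
                                         ifelse(d < 0, "enriched_in_B", "none")),
                      mode = "longitudinal", timepoint = "integrated",
                      stringsAsFactors = FALSE)
    attr(out, "n_permutations") <- as.integer(n_permutations)
    attr(out, "networks") <- list(control = chain$net_a, stress = chain$net_b)
    out
  })
}
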