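#' Integrate per-timepoint networks into one condition network
#'
#' Weighted edgewise average over a shared taxon universe (union; taxa
#' missing from a timepoint contribute zero weight for their edges). The
#' default weights are inverse-variance weights from the Fisher-z sampling
#' variance of a correlation, \eqn{1/(n_t - 3)}, i.e. \eqn{w_t = n_t - 3}
#' with `n_t` the sample count recorded in each network's provenance;
#' explicit `weights` override them.
#'
#' @param networks list of [correlation_network]s of one condition across
#'   timepoints.
#' @param weights optional numeric vector, one weight per network.
#' @return A [correlation_network] with provenance listing the contributing
#'   networks.
#' @export
integrate_networks <- function(networks, weights = NULL) {
  if (!length(networks)) stop_user("empty network list")
  conds <- unique(unlist(lapply(networks, function(x) x$condition %||% NA_character_)))
  conds <- conds[!is.na(conds)]
  if (length(conds) > 1) stop_user("condition mismatch across networks: ",
                                   paste(conds, collapse = " vs "))
  if (is.null(weights)) {
    weights <- vapply(networks, function(x) {
      n_t <- x$provenance$n_samples
      if (is.null(n_t) || n_t <= 3) 1 else n_t - 3
    }, numeric(1))
  }
  stopifnot(length(weights) == length(networks), all(weights >= 0), any(weights > 0))
  taxa <- sort(unique(unlist(lapply(networks, `[[`, "taxon_ids"))))
  num <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  den <- num
  for (k in seq_along(networks)) {
    idx <- networks[[k]]$taxon_ids
    num[idx, idx] <- num[idx, idx] + weights[k] * networks[[k]]$adjacency
    den[idx, idx] <- den[idx, idx] + weights[k]
  }
  a <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  diag(a) <- 1
  correlation_network(a, condition = if (length(conds)) conds else NULL,
                      provenance = list(method = "integrate_networks",
                                        weights = weights,
                                        n_networks = length(networks),
                                        contributing = lapply(networks, `[[`, "provenance")))
}

#' Network topology and node centralities
#'
#' Binarizes the network at `|a_ij| >= edge_threshold` (i != j) and reports
#' per-node degree, strength (sum of |a| over supra-threshold edges),
#' betweenness and closeness on the resulting undirected graph, plus
#' network-level mean degree, edge count and density.
#'
#' @param network a [correlation_network].
#' @param edge_threshold absolute-correlation threshold in \[0, 1)
#'   (default 0.3).
#' @return list(nodes = per-node data.frame, summary = list, edge_threshold).
#' @export
topology <- function(network, edge_threshold = 0.3) {
  stopifnot(edge_threshold >= 0, edge_threshold < 1)
  a <- network$adjacency
  n <- nrow(a)
  adj <- abs(a) >= edge_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  deg <- igraph::degree(g)
  strength <- rowSums(abs(a) * adj)
  btw <- igraph::betweenness(g)
  clo <- suppressWarnings(igraph::closeness(g, mode = "all"))
  clo[!is.finite(clo)] <- 0  # isolated nodes
  nodes <- data.frame(node = network$taxon_ids, degree = unname(deg),
                      strength = unname(strength), betweenness = unname(btw),
                      closeness = unname(clo), stringsAsFactors = FALSE)
  n_edges <- sum(adj) / 2
  list(nodes = nodes,
       summary = list(mean_degree = mean(deg), n_edges = n_edges,
                      density = if (n > 1) n_edges / (n * (n - 1) / 2) else 0),
       edge_threshold = edge_threshold)
}

#' Compare node-level topology between two networks
#'
#' Per shared metric, a two-sample Mann-Whitney test of the node-level
#' distributions plus the difference of means (network A minus network B).
#'
#' @param report_a,report_b outputs of [topology].
#' @return data.frame with columns metric, mean_a, mean_b, mean_difference,
#'   p_value.
#' @export
compare_topology <- function(report_a, report_b) {
  if (!length(intersect(report_a$nodes$node, report_b$nodes$node))) {
    stop_user("topology reports have disjoint node sets")
  }
  metrics_a <- setdiff(names(report_a$nodes), "node")
  metrics_b <- setdiff(names(report_b$nodes), "node")
  only <- c(setdiff(metrics_a, metrics_b), setdiff(metrics_b, metrics_a))
  if (length(only)) warning("metric(s) present in one report only, skipped: ",
                            paste(only, collapse = ", "))
  shared <- intersect(metrics_a, metrics_b)
  rows <- lapply(shared, function(mt) {
    va <- report_a$nodes[[mt]]
    vb <- report_b$nodes[[mt]]
    p <- suppressWarnings(stats::wilcox.test(va, vb)$p.value)
    if (is.na(p)) p <- 1
    data.frame(metric = mt, mean_a = mean(va), mean_b = mean(vb),
               mean_difference = mean(va) - mean(vb), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a network as an edge list importable by graph viewers
#'
#' @param network a [correlation_network].
#' @param path output TSV path (columns source, target, weight).
#' @param edge_threshold minimum |a_ij| for an edge to be written.
#' @export
write_edge_list <- function(network, path, edge_threshold = 0.3) {
  a <- network$adjacency
  idx <- which(upper.tri(a) & abs(a) >= edge_threshold, arr.ind = TRUE)
  df <- data.frame(source = rownames(a)[idx[, 1]],
                   target = colnames(a)[idx[, 2]],
                   weight = a[idx], stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target), , drop = FALSE]
  write_result(df, path)
}
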