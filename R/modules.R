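#' Detect co-occurrence modules via topological overlap clustering
#'
#' WGCNA-style: signed soft adjacency
#' \eqn{s_{ij} = ((1 + a_{ij})/2)^{\beta}}, topological overlap similarity,
#' average-linkage hierarchical clustering on the TOM dissimilarity, and a
#' static tree cut at `cut_height`. Clusters smaller than
#' `min_module_size` are relabeled `"grey"` (unassigned). Deterministic:
#' there is no random initialization anywhere in this path.
#'
#' @param network a [correlation_network].
#' @param soft_power soft-thresholding power (default 6, the conventional
#'   signed-network default).
#' @param min_module_size smallest retained module (default 5).
#' @param cut_height static cut height on TOM dissimilarity (default 0.9).
#' @return An object of class `module_partition`: list(modules = named
#'   character vector node -> module label, n, sizes).
#' @export
detect_modules <- function(network, soft_power = 6L, min_module_size = 5L,
                           cut_height = 0.9) {
  a <- network$adjacency
  n <- nrow(a)
  if (n < min_module_size) {
    warning("fewer nodes than min_module_size; returning a single module")
    modules <- stats::setNames(rep("M1", n), network$taxon_ids)
    return(new_module_partition(modules))
  }
  s <- ((1 + a) / 2)^soft_power
  diag(s) <- 0
  k <- rowSums(s)
  num <- s %*% s + s
  den <- outer(k, k, pmin) + 1 - s
  tom <- num / den
  diag(tom) <- 1
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  modules <- rep("grey", n)
  if (length(keep)) {
    # label modules M1, M2, ... by decreasing size; ties by first member
    ord <- order(-as.integer(sizes[keep]),
                 vapply(keep, function(g) min(which(cl == as.integer(g))), numeric(1)))
    for (r in seq_along(ord)) {
      modules[cl == as.integer(keep[ord[r]])] <- sprintf("M%d", r)
    }
  }
  names(modules) <- network$taxon_ids
  new_module_partition(modules)
}

new_module_partition <- function(modules) {
  stopifnot(!is.null(names(modules)), !anyNA(modules))
  structure(list(modules = modules, n = length(modules),
                 sizes = table(modules)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d nodes, %d modules (%s)\n", x$n,
              sum(names(x$sizes) != "grey"),
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", ")))
  invisible(x)
}

#' Node connection strength
#'
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}: the sum of a node's correlations with
#' all other nodes (self-term excluded).
#'
#' @param network a [correlation_network].
#' @return Named numeric vector of k_i.
#' @export
connection_strength <- function(network) {
  a <- network$adjacency
  stats::setNames(rowSums(a) - diag(a), network$taxon_ids)
}

#' Within-minus-between module connectivity
#'
#' For node i in module M:
#' \eqn{\sum_{j \in M, j \ne i} a_{ij} - \sum_{j \notin M} a_{ij}}, the
#' node's within-module connectivity minus its out-of-module connectivity.
#' When all of a node's connections lie inside its module this equals
#' \eqn{k_i}; for a singleton module it equals \eqn{-k_i}.
#'
#' @param network a [correlation_network].
#' @param partition a `module_partition` covering all network nodes.
#' @return Named numeric vector.
#' @export
module_importance <- function(network, partition) {
  a <- network$adjacency
  taxa <- network$taxon_ids
  missing <- setdiff(taxa, names(partition$modules))
  if (length(missing)) stop_user("node(s) missing from partition: ",
                                 paste(utils::head(missing, 5), collapse = ", "))
  mod <- partition$modules[taxa]
  same <- outer(mod, mod, `==`)
  diag(same) <- FALSE
  off <- a
  diag(off) <- 0
  within <- rowSums(off * same)
  between <- rowSums(off * !same)
  stats::setNames(within - between, taxa)
}
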