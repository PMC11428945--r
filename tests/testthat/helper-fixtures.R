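# Small fixture builders used across the suite; everything is generated in
# code at test time.

make_table <- function(counts, samples = NULL, taxa = NULL, taxonomy = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- samples %||% sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- taxa %||% sprintf("t%02d", seq_len(ncol(m)))
  count_table(m, taxonomy = taxonomy)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random symmetric correlation-like adjacency with unit diagonal
random_network <- function(n, seed, scale = 0.6) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n, -scale, scale), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  correlation_network(a)
}

# block-structured "true" network: within-block rho, between 0
block_network <- function(sizes, rho, n_extra = 0) {
  n <- sum(sizes) + n_extra
  assign <- c(rep(seq_along(sizes), sizes), rep(NA, n_extra))
  a <- diag(1, n)
  for (k in seq_along(sizes)) {
    idx <- which(!is.na(assign) & assign == k)
    a[idx, idx] <- rho
  }
  diag(a) <- 1
  dimnames(a) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
  list(network = correlation_network(a),
       assign = stats::setNames(ifelse(is.na(assign), "grey",
                                       paste0("B", assign)),
                                rownames(a)))
}

make_partition <- function(labels, nodes = names(labels)) {
  names(labels) <- nodes
  netshiftr:::new_module_partition(labels)
}

# simple two-arm single-timepoint simulation used in several tests
sim_two_arm <- function(seed, n_taxa = 24L, n_per_arm = 30L,
                        module_sizes = c(6L, 6L), rho = 0.8,
                        drivers = c(1L, 2L, 7L, 8L), effect = 1.5,
                        rewire = TRUE, n_timepoints = 1L, depth = 20000L) {
  cfg <- simulation_config(n_taxa = n_taxa,
                           n_samples_per_group_per_timepoint = n_per_arm,
                           n_timepoints = n_timepoints,
                           module_sizes = module_sizes,
                           basis_correlation_within_module = rho,
                           driver_taxa = drivers,
                           driver_log2_effect = effect,
                           driver_rewire = rewire,
                           sequencing_depth_mean = depth,
                           seed = seed)
  simulate_counts(cfg)
}

split_arms <- function(sim) netshiftr:::split_by_group(sim$table, sim$metadata)

# economy analysis settings used in permutation-heavy tests: edge threshold
# midway between the planted within-module correlation (0.8) and its
# mixed-arm attenuation (~0.4); exclusion rounds off for speed
economy_control <- function(edge_threshold = 0.45) {
  nmss_control(n_exclusion_rounds = 0L, permutation_inner_iterations = 3L,
               edge_threshold = edge_threshold)
}
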