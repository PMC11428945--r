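#' Configuration for the synthetic community generator
#'
#' Defaults describe a genus-level longitudinal two-arm cohort: 150 genera,
#' 30 samples per group per timepoint over 3 timepoints, four correlated
#' modules, and 8 "driver" genera whose mean abundance is shifted and whose
#' correlation structure is rewired in the stress arm.
#'
#' @param n_taxa number of taxa (default 150).
#' @param n_samples_per_group_per_timepoint samples per arm per timepoint
#'   (default 30).
#' @param n_timepoints number of sampling timepoints (default 3).
#' @param module_sizes sizes of the planted correlation blocks; their sum
#'   must not exceed `n_taxa` (remaining taxa are uncorrelated background).
#' @param basis_correlation_within_module within-block basis correlation in
#'   (-1, 1) (default 0.7); between-block basis correlation is 0.
#' @param driver_taxa indices of planted driver taxa.
#' @param driver_log2_effect log2 fold change of driver mean abundance in
#'   stress vs control (default 1.5).
#' @param driver_rewire if `TRUE` (default) drivers additionally move to the
#'   next correlation block in the stress arm, so the network structure (not
#'   just the mean) differs between conditions.
#' @param sequencing_depth_mean mean library size (default 45000; chosen to
#'   exceed the default rarefaction depth of 31731).
#' @param sequencing_depth_dispersion coefficient of variation of the
#'   lognormal-rounded per-sample depth law (default 0.3).
#' @param base_log_mean_sd SD of per-taxon baseline log-mean abundances
#'   (default 1.0) -- controls how uneven the community is.
#' @param taxon_log_sd per-taxon lognormal SD of latent abundances
#'   (default 1.0).
#' @param timepoint_labels ordered timepoint labels; defaults to the
#'   study-style month labels for 3 timepoints.
#' @param seed integer seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 150L,
                              n_samples_per_group_per_timepoint = 30L,
                              n_timepoints = 3L,
                              module_sizes = c(25L, 20L, 15L, 10L),
                              basis_correlation_within_module = 0.7,
                              driver_taxa = c(1L, 2L, 26L, 27L, 46L, 47L, 61L, 62L),
                              driver_log2_effect = 1.5,
                              driver_rewire = TRUE,
                              sequencing_depth_mean = 45000L,
                              sequencing_depth_dispersion = 0.3,
                              base_log_mean_sd = 1.0,
                              taxon_log_sd = 1.0,
                              timepoint_labels = NULL,
                              seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa),
              n_samples_per_group_per_timepoint = as.integer(n_samples_per_group_per_timepoint),
              n_timepoints = as.integer(n_timepoints),
              module_sizes = as.integer(module_sizes),
              basis_correlation_within_module = basis_correlation_within_module,
              driver_taxa = as.integer(driver_taxa),
              driver_log2_effect = driver_log2_effect,
              driver_rewire = isTRUE(driver_rewire),
              sequencing_depth_mean = as.integer(sequencing_depth_mean),
              sequencing_depth_dispersion = sequencing_depth_dispersion,
              base_log_mean_sd = base_log_mean_sd,
              taxon_log_sd = taxon_log_sd,
              timepoint_labels = timepoint_labels,
              seed = as.integer(seed))
  if (cfg$n_taxa < 2L) stop_user("n_taxa must be >= 2")
  if (sum(cfg$module_sizes) > cfg$n_taxa) {
    stop_user("sum(module_sizes) exceeds n_taxa")
  }
  if (length(cfg$driver_taxa) &&
      (min(cfg$driver_taxa) < 1L || max(cfg$driver_taxa) > cfg$n_taxa)) {
    stop_user("driver_taxa indices out of range 1..n_taxa")
  }
  rho <- cfg$basis_correlation_within_module
  if (rho <= -1 || rho >= 1) stop_user("basis_correlation_within_module must be in (-1, 1)")
  if (length(cfg$module_sizes)) {
    m <- max(cfg$module_sizes)
    if (m > 1L && rho < -1 / (m - 1)) {
      stop_user(sprintf(
        "requested within-module correlation %.3f makes the basis matrix non-PSD for a block of %d; nearest PSD value is %.3f",
        rho, m, -1 / (m - 1)))
    }
  }
  if (cfg$sequencing_depth_mean < 1L) stop_user("sequencing_depth_mean must be >= 1")
  if (is.null(cfg$timepoint_labels)) {
    base_labels <- c("07_2022", "09_2022", "10_2022")
    cfg$timepoint_labels <- if (cfg$n_timepoints <= 3L) {
      base_labels[seq_len(cfg$n_timepoints)]
    } else {
      sprintf("tp%02d", seq_len(cfg$n_timepoints))
    }
  }
  if (length(cfg$timepoint_labels) != cfg$n_timepoints) {
    stop_user("timepoint_labels length must equal n_timepoints")
  }
  class(cfg) <- "simulation_config"
  cfg
}

module_assignment_from_config <- function(cfg, condition = c("control", "stress")) {
  condition <- match.arg(condition)
  assign <- rep(NA_character_, cfg$n_taxa)
  idx <- 1L
  for (k in seq_along(cfg$module_sizes)) {
    assign[idx:(idx + cfg$module_sizes[k] - 1L)] <- sprintf("M%d", k)
    idx <- idx + cfg$module_sizes[k]
  }
  if (condition == "stress" && cfg$driver_rewire && length(cfg$module_sizes) >= 2L) {
    nk <- length(cfg$module_sizes)
    for (d in cfg$driver_taxa) {
      cur <- assign[d]
      k <- if (is.na(cur)) 0L else as.integer(sub("^M", "", cur))
      assign[d] <- sprintf("M%d", (k %% nk) + 1L)
    }
  }
  assign
}

basis_correlation_from_assignment <- function(assign, rho) {
  n <- length(assign)
  C <- diag(1, n)
  for (lab in unique(assign[!is.na(assign)])) {
    members <- which(!is.na(assign) & assign == lab)
    if (length(members) > 1L) C[members, members] <- rho
  }
  diag(C) <- 1
  C
}

default_taxonomy <- function(cfg, taxa, assign) {
  phyla <- c("Firmicutes", "Bacteroidota", "Actinobacteriota", "Spirochaetota")
  fam <- ifelse(is.na(assign), "Family_bg", paste0("Family_", assign))
  data.frame(taxon_id = taxa,
             Phylum = phyla[(seq_along(taxa) - 1L) %% length(phyla) + 1L],
             Family = fam,
             Genus = taxa,
             stringsAsFactors = FALSE)
}

simulate_arm <- function(n, mu, Sigma, depth_mean, depth_cv, taxa) {
  z <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  if (n == 1L) z <- matrix(z, nrow = 1L)
  x <- exp(z)
  p <- x / rowSums(x)
  sdlog <- sqrt(log(1 + depth_cv^2))
  meanlog <- log(depth_mean) - sdlog^2 / 2
  depths <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1L, depths[i], p[i, ])[, 1L],
                     numeric(length(taxa))))
  colnames(counts) <- taxa
  list(counts = counts, latent = z, depths = depths)
}

#' Simulate a longitudinal two-arm community with planted structure
#'
#' Latent basis abundances are multivariate log-normal with block correlation
#' (blocks = planted modules, within-block correlation from the config,
#' between-block 0). In the stress arm driver taxa have their log2 mean
#' shifted by `driver_log2_effect` and, if `driver_rewire`, their correlation
#' rows moved to the next block. Per-sample depth follows a lognormal-rounded
#' law; observed counts are multinomial draws from the normalized latent
#' composition, so each row sum equals its drawn depth exactly.
#'
#' @param config a [simulation_config].
#' @return list with elements `table` (a [count_table] with taxonomy),
#'   `metadata` (data.frame), and `truth` (basis correlation matrices,
#'   per-condition module assignments, driver taxon IDs and per-sample
#'   latent log abundances).
#' @export
simulate_counts <- function(config) {
  simulate_with_multipliers(config, rep(1, config$n_timepoints))
}

#' Simulate a perturbation-and-recovery trajectory
#'
#' The driver effect (mean shift and, when configured, correlation
#' rewiring) is applied in full at `perturbed_timepoint`, scaled by
#' `1 - recovery_fraction` at later timepoints, and absent earlier --
#' emulating a community perturbed by an acute stressor whose composition
#' then relaxes back toward baseline.
#'
#' @param config a [simulation_config].
#' @param perturbed_timepoint one of `config$timepoint_labels`.
#' @param recovery_fraction in \[0, 1\]: 1 = full recovery after the
#'   perturbed timepoint, 0 = effect persists.
#' @return As [simulate_counts].
#' @export
simulate_resilience_trajectory <- function(config, perturbed_timepoint,
                                           recovery_fraction) {
  if (!perturbed_timepoint %in% config$timepoint_labels) {
    stop_user("unknown timepoint label: ", perturbed_timepoint)
  }
  stopifnot(recovery_fraction >= 0, recovery_fraction <= 1)
  k <- match(perturbed_timepoint, config$timepoint_labels)
  mult <- numeric(config$n_timepoints)
  mult[k] <- 1
  if (k < config$n_timepoints) mult[(k + 1):config$n_timepoints] <- 1 - recovery_fraction
  simulate_with_multipliers(config, mult)
}

simulate_with_multipliers <- function(cfg, multipliers) {
  stopifnot(length(multipliers) == cfg$n_timepoints)
  with_seed(cfg$seed, {
    taxa <- sprintf("g%03d", seq_len(cfg$n_taxa))
    assign_c <- module_assignment_from_config(cfg, "control")
    assign_s <- module_assignment_from_config(cfg, "stress")
    rho <- cfg$basis_correlation_within_module
    C_c <- basis_correlation_from_assignment(assign_c, rho)
    C_s <- basis_correlation_from_assignment(assign_s, rho)
    base_mu <- stats::rnorm(cfg$n_taxa, 0, cfg$base_log_mean_sd)
    sd_vec <- rep(cfg$taxon_log_sd, cfg$n_taxa)
    Sigma_of <- function(C) (sd_vec %o% sd_vec) * C

    n <- cfg$n_samples_per_group_per_timepoint
    counts_all <- NULL; latent_all <- NULL
    md <- list()
    for (t in seq_len(cfg$n_timepoints)) {
      m <- multipliers[t]
      mu_s <- base_mu
      mu_s[cfg$driver_taxa] <- mu_s[cfg$driver_taxa] + m * cfg$driver_log2_effect * log(2)
      C_t <- (1 - m) * C_c + m * C_s
      for (g in c("control", "stress")) {
        mu <- if (g == "control") base_mu else mu_s
        C_use <- if (g == "control") C_c else C_t
        arm <- simulate_arm(n, mu, Sigma_of(C_use),
                            cfg$sequencing_depth_mean,
                            cfg$sequencing_depth_dispersion, taxa)
        ids <- sprintf("%s_%s_%02d", substr(g, 1, 4), cfg$timepoint_labels[t], seq_len(n))
        rownames(arm$counts) <- ids
        rownames(arm$latent) <- ids
        counts_all <- rbind(counts_all, arm$counts)
        latent_all <- rbind(latent_all, arm$latent)
        md[[length(md) + 1L]] <- data.frame(
          sample_id = ids, group = g,
          sex = rep(c("female", "castrated_male"), length.out = n),
          pen = sprintf("pen_%s_%d", substr(g, 1, 4), (seq_len(n) - 1L) %% 4L + 1L),
          timepoint = cfg$timepoint_labels[t],
          stringsAsFactors = FALSE)
      }
    }
    metadata <- validate_metadata(do.call(rbind, md))
    metadata$timepoint <- factor(as.character(metadata$timepoint),
                                 levels = cfg$timepoint_labels, ordered = TRUE)
    colnames(latent_all) <- taxa
    dimnames(C_c) <- dimnames(C_s) <- list(taxa, taxa)
    names(assign_c) <- names(assign_s) <- taxa
    truth <- list(
      basis_correlation = list(control = C_c, stress = C_s),
      module_assignment = list(control = assign_c, stress = assign_s),
      drivers = taxa[cfg$driver_taxa],
      effect_multiplier = stats::setNames(multipliers, cfg$timepoint_labels),
      latent_log_abundance = latent_all)
    list(table = count_table(counts_all,
                             taxonomy = default_taxonomy(cfg, taxa, assign_c)),
         metadata = metadata,
         truth = truth)
  })
}
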