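test_that("same config and seed give bit-identical output", {
  s1 <- sim_two_arm(11, n_taxa = 12L, n_per_arm = 8L, module_sizes = c(4L),
                    drivers = 1L, depth = 3000L)
  s2 <- sim_two_arm(11, n_taxa = 12L, n_per_arm = 8L, module_sizes = c(4L),
                    drivers = 1L, depth = 3000L)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$metadata, s2$metadata)
})

test_that("counts are non-negative integers and depths follow the configured law", {
  sim <- sim_two_arm(3, n_taxa = 20L, n_per_arm = 40L, depth = 10000L,
                     module_sizes = c(5L), drivers = integer(0), effect = 0,
                     rewire = FALSE)
  m <- sim$table$counts
  expect_true(all(m >= 0) && all(m == round(m)))
  depths <- rowSums(m)
  # lognormal-rounded with mean 10000, CV 0.3
  expect_gt(mean(depths), 10000 * 0.85)
  expect_lt(mean(depths), 10000 * 1.15)
  expect_gt(stats::sd(depths) / mean(depths), 0.15)
})

test_that("planted block correlation is recoverable from latent log abundances", {
  cfg <- simulation_config(n_taxa = 10L, n_samples_per_group_per_timepoint = 5000L,
                           n_timepoints = 1L, module_sizes = c(5L),
                           basis_correlation_within_module = 0.7,
                           driver_taxa = integer(0), driver_rewire = FALSE,
                           sequencing_depth_mean = 5000L, seed = 5)
  sim <- simulate_counts(cfg)
  L <- sim$truth$latent_log_abundance[sim$metadata$group == "control", ]
  cc <- stats::cor(L)
  truth <- sim$truth$basis_correlation$control
  expect_lt(max(abs(cc - truth)), 0.05)
})

test_that("zero planted correlation yields near-zero empirical correlations", {
  cfg <- simulation_config(n_taxa = 5L, n_samples_per_group_per_timepoint = 2000L,
                           n_timepoints = 1L, module_sizes = c(5L),
                           basis_correlation_within_module = 0,
                           driver_taxa = integer(0), driver_rewire = FALSE,
                           sequencing_depth_mean = 5000L, seed = 6)
  sim <- simulate_counts(cfg)
  L <- sim$truth$latent_log_abundance[sim$metadata$group == "control", ]
  cc <- stats::cor(L); diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.1)
})

test_that("arms are exchangeable when no effect is planted", {
  # null backbone for the downstream type-I tests: per-taxon two-sample
  # t-tests on log relative abundance should reject at ~alpha
  rejections <- 0L; total <- 0L
  for (s in 1:5) {
    sim <- sim_two_arm(s, n_taxa = 30L, n_per_arm = 25L, module_sizes = c(6L),
                       drivers = integer(0), effect = 0, rewire = FALSE,
                       depth = 8000L)
    rel <- log(relative_abundance(sim$table) + 1e-6)
    grp <- sim$metadata$group[match(rownames(rel), sim$metadata$sample_id)]
    p <- apply(rel, 2, function(v) stats::t.test(v[grp == "control"],
                                                 v[grp == "stress"])$p.value)
    rejections <- rejections + sum(p < 0.05)
    total <- total + length(p)
  }
  expect_lte(rejections / total, 0.08)
})

test_that("resilience trajectory scales the driver effect per timepoint", {
  base <- list(n_taxa = 10L, n_samples_per_group_per_timepoint = 500L,
               n_timepoints = 3L, module_sizes = c(4L),
               driver_taxa = 9L, driver_log2_effect = 2,
               driver_rewire = FALSE, sequencing_depth_mean = 5000L)
  realized_log2 <- function(sim, tp) {
    L <- sim$truth$latent_log_abundance
    md <- sim$metadata
    sel <- function(g) L[md$sample_id[md$group == g & md$timepoint == tp], "g009"]
    (mean(sel("stress")) - mean(sel("control"))) / log(2)
  }
  cfg <- do.call(simulation_config, c(base, list(seed = 21)))
  full_rec <- simulate_resilience_trajectory(cfg, "09_2022", recovery_fraction = 1)
  expect_lt(abs(realized_log2(full_rec, "07_2022") - 0), 0.15)  # pre-stressor
  expect_lt(abs(realized_log2(full_rec, "09_2022") - 2), 0.15)  # acute
  expect_lt(abs(realized_log2(full_rec, "10_2022") - 0), 0.15)  # recovered

  none <- simulate_resilience_trajectory(cfg, "09_2022", recovery_fraction = 0)
  expect_lt(abs(realized_log2(none, "10_2022") - 2), 0.15)      # persists

  half <- simulate_resilience_trajectory(cfg, "09_2022", recovery_fraction = 0.5)
  expect_lt(abs(realized_log2(half, "10_2022") - 1), 0.15)      # half effect

  expect_error(simulate_resilience_trajectory(cfg, "nope", 0.5), "timepoint")
})

test_that("invalid configurations are rejected with actionable messages", {
  expect_error(simulation_config(n_taxa = 10L, module_sizes = c(8L, 8L),
                                 driver_taxa = integer(0)),
               "module_sizes")
  expect_error(simulation_config(n_taxa = 20L, module_sizes = c(5L),
                                 driver_taxa = 25L), "out of range")
  expect_error(simulation_config(n_taxa = 20L, module_sizes = c(10L),
                                 driver_taxa = 1L,
                                 basis_correlation_within_module = -0.5),
               "PSD")
})
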