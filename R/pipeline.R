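pipeline_defaults <- function() {
  list(
    output_dir = "results/pipeline",
    seed = 1L,
    simulation = list(),   # overrides for simulation_config()
    preprocess = list(min_fraction = 1e-6, depth = 31731L, rank = "Genus"),
    diversity = list(n_permutations = 999L),
    network = list(edge_threshold = 0.3),
    netmoss = list(n_permutations = 200L,
                   n_inner_iterations = 20L,
                   permutation_inner_iterations = 5L),
    evaluate = list(n_folds = 10L, panel_size = 10L, alpha = 0.05)
  )
}

merge_validated <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_user("unknown config key(s)", if (nzchar(path)) paste0(" under '", path, "'"),
              ": ", paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && nm != "simulation") {
      defaults[[nm]] <- merge_validated(defaults[[nm]], user[[nm]],
                                        paste0(path, if (nzchar(path)) ".", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected
#' before any stage runs. The `simulation` block takes any argument of
#' [simulation_config]; other blocks hold stage parameters (rarefaction
#' depth, edge threshold, permutation counts, fold count, panel size).
#'
#' @param config YAML path, named list, or `NULL` for all defaults.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_user("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  cfg <- merge_validated(defaults, config)
  sim_ok <- names(formals(simulation_config))
  unknown <- setdiff(names(cfg$simulation), sim_ok)
  if (length(unknown)) stop_user("unknown simulation key(s): ",
                                 paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop_user("stage '", name, "' failed: ", conditionMessage(e)))
  message(sprintf("[netshiftr] stage %-12s done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Stages in order: simulate, preprocess (singleton and low-abundance
#' filters, rarefaction), diversity (alpha suite, Bray-Curtis, PCoA,
#' Whittaker per group and timepoint, PERMANOVA for sex), networks
#' (per-condition integrated SparCC networks, topology comparison),
#' biomarkers (per-timepoint and longitudinal module-shift runs with
#' permutation FDR), and evaluation (cross-validated ROC of the top-scoring
#' panel, benchmark against planted truth). All outputs are TSV/JSON under
#' `config$output_dir`, accompanied by a provenance record (parameters,
#' derived per-stage seeds, package version, output hashes). Identical
#' config and seed give identical artifacts.
#'
#' @param config a [pipeline_config] (or anything it accepts).
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(cfg$output_dir, f)
  seeds <- list(simulate = derive_seed(cfg$seed, "simulate"),
                rarefy = derive_seed(cfg$seed, "rarefy"),
                diversity = derive_seed(cfg$seed, "diversity"),
                netmoss = derive_seed(cfg$seed, "netmoss"),
                evaluate = derive_seed(cfg$seed, "evaluate"))

  sim <- run_stage("simulate", {
    sim_cfg <- do.call(simulation_config,
                       c(cfg$simulation, list(seed = seeds$simulate)))
    s <- simulate_counts(sim_cfg)
    write_count_table(s$table, out_path("counts.tsv"))
    utils::write.table(s$metadata, out_path("metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(drivers = s$truth$drivers,
                              module_assignment = as.list(s$truth$module_assignment$control)),
                         out_path("ground_truth.json"), auto_unbox = TRUE)
    s
  })

  prep <- run_stage("preprocess", {
    st1 <- remove_singletons(sim$table)
    st2 <- filter_low_abundance(st1$table, fraction = cfg$preprocess$min_fraction)
    st3 <- rarefy(st2$table, depth = cfg$preprocess$depth, seed = seeds$rarefy)
    report <- list(order = c("remove_singletons", "filter_low_abundance", "rarefy"),
                   n_taxa_in = st1$report$n_taxa_in,
                   n_removed_singletons = st1$report$n_removed_singletons,
                   n_removed_low_abundance = st2$report$n_removed_low_abundance,
                   n_samples_dropped = st3$report$n_samples_dropped,
                   rarefaction_depth = st3$report$rarefaction_depth)
    jsonlite::write_json(report, out_path("filter_report.json"), auto_unbox = TRUE)
    md <- sim$metadata[sim$metadata$sample_id %in% rownames(st3$table$counts), ,
                       drop = FALSE]
    list(table = st3$table, metadata = md, report = report)
  })

  div <- run_stage("diversity", {
    alpha <- alpha_suite(prep$table)
    write_result(alpha, out_path("alpha_diversity.tsv"))
    bc <- bray_curtis(prep$table)
    utils::write.table(round(bc, 6), out_path("bray_curtis.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    ord <- pcoa_ordination(bc, n_axes = 2L)
    write_result(data.frame(sample_id = rownames(ord$coordinates),
                            ord$coordinates), out_path("pcoa.tsv"))
    al <- align_samples(prep$table, prep$metadata)
    perm_sex <- if ("sex" %in% names(al$metadata) &&
                    length(unique(al$metadata$sex)) > 1) {
      permanova(bc, al$metadata$sex,
                n_permutations = cfg$diversity$n_permutations,
                seed = seeds$diversity)
    } else NULL
    if (!is.null(perm_sex)) {
      jsonlite::write_json(perm_sex, out_path("permanova_sex.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    groups <- expand.grid(group = levels(al$metadata$group),
                          timepoint = levels(al$metadata$timepoint),
                          stringsAsFactors = FALSE)
    groups$whittaker <- vapply(seq_len(nrow(groups)), function(i) {
      ids <- al$metadata$sample_id[al$metadata$group == groups$group[i] &
                                     al$metadata$timepoint == groups$timepoint[i]]
      if (length(ids)) whittaker_beta(prep$table, ids) else NA_real_
    }, numeric(1))
    write_result(groups, out_path("whittaker_beta.tsv"))
    list(alpha = alpha, bray = bc, pcoa = ord, permanova_sex = perm_sex,
         whittaker = groups)
  })

  ctrl <- nmss_control(
    n_inner_iterations = cfg$netmoss$n_inner_iterations,
    edge_threshold = cfg$network$edge_threshold,
    permutation_inner_iterations = cfg$netmoss$permutation_inner_iterations)

  nets <- run_stage("networks", {
    al <- align_samples(prep$table, prep$metadata)
    by_cond <- lapply(stats::setNames(c("control", "stress"), c("control", "stress")),
                      function(g) {
                        tabs <- lapply(levels(al$metadata$timepoint), function(tp) {
                          ids <- al$metadata$sample_id[al$metadata$group == g &
                                                         al$metadata$timepoint == tp]
                          count_table(al$table$counts[ids, , drop = FALSE])
                        })
                        longitudinal_networks(tabs, g, ctrl,
                                              ctrl$n_inner_iterations,
                                              derive_seed(cfg$seed, paste0("net_", g)))
                      })
    topo <- lapply(by_cond, topology, edge_threshold = cfg$network$edge_threshold)
    cmp <- compare_topology(topo$control, topo$stress)
    write_result(cmp, out_path("topology_comparison.tsv"))
    for (g in names(by_cond)) {
      write_edge_list(by_cond[[g]], out_path(paste0("network_", g, "_edges.tsv")),
                      edge_threshold = cfg$network$edge_threshold)
    }
    list(networks = by_cond, topology = topo, comparison = cmp)
  })

  bio <- run_stage("biomarkers", {
    per_tp <- run_per_timepoint(prep$table, prep$metadata,
                                n_permutations = cfg$netmoss$n_permutations,
                                seed = seeds$netmoss, control = ctrl)
    long <- run_longitudinal(prep$table, prep$metadata,
                             n_permutations = cfg$netmoss$n_permutations,
                             seed = seeds$netmoss, control = ctrl)
    all_rows <- rbind(do.call(rbind, per_tp), long)
    write_result(all_rows[order(all_rows$mode, all_rows$timepoint,
                                all_rows$q_value, all_rows$taxon), ],
                 out_path("biomarkers.tsv"))
    list(per_timepoint = per_tp, longitudinal = long)
  })

  ev <- run_stage("evaluate", {
    long <- bio$longitudinal
    panel <- long$taxon[order(long$q_value, -long$nmss)][seq_len(
      min(cfg$evaluate$panel_size, nrow(long)))]
    roc <- netroc(prep$table, prep$metadata, panel,
                  n_folds = cfg$evaluate$n_folds, seed = seeds$evaluate)
    jsonlite::write_json(roc[c("auc", "fold_aucs", "mean_fold_auc", "n_folds",
                               "panel")],
                         out_path("netroc.json"), auto_unbox = TRUE, digits = NA)
    bench <- benchmark_against_truth(long, sim$truth, alpha = cfg$evaluate$alpha)
    write_result(bench, out_path("benchmark.tsv"))
    list(roc = roc, benchmark = bench, panel = panel)
  })

  prov <- list(package = "netshiftr",
               version = as.character(utils::packageVersion("netshiftr")),
               config = unclass(cfg), derived_seeds = seeds,
               economy_mode = list(
                 permutation_inner_iterations = ctrl$permutation_inner_iterations,
                 n_permutations = cfg$netmoss$n_permutations),
               output_hashes = as.list(tools::md5sum(
                 list.files(cfg$output_dir, full.names = TRUE,
                            pattern = "\\.(tsv|json)$"))))
  names(prov$output_hashes) <- basename(names(prov$output_hashes))
  jsonlite::write_json(prov, out_path("provenance.json"), auto_unbox = TRUE)

  invisible(list(simulation = sim, preprocess = prep, diversity = div,
                 networks = nets, biomarkers = bio, evaluation = ev,
                 provenance = prov))
}
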