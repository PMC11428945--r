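two_block_pair <- function(seed = 1, move = NULL) {
  # networks A and B over the same taxa; optionally move one node's block in B
  ba <- block_network(c(5L, 5L), rho = 0.8)
  bb <- block_network(c(5L, 5L), rho = 0.8)
  if (!is.null(move)) {
    a <- bb$network$adjacency
    a[move, ] <- a[, move] <- 0
    other <- which(bb$assign == "B2")
    a[move, other] <- a[other, move] <- 0.8
    diag(a) <- 1
    bb$network <- correlation_network(a)
    bb$assign[move] <- "B2"
  }
  list(net_a = ba$network, part_a = make_partition(ba$assign),
       net_b = bb$network, part_b = make_partition(bb$assign))
}

test_that("differential module distance is Jaccard on member sets", {
  x <- two_block_pair()
  d <- differential_module_distance(x$net_a, x$part_a, x$net_b, x$part_b)
  # identical partitions: every module matches itself at distance 0
  expect_equal(unname(diag(d$D[c("B1", "B2"), c("B1", "B2")])), c(0, 0))
  expect_true(all(d$D[upper.tri(d$D) | lower.tri(d$D)] > 0))
  expect_true(all(d$D >= 0))
  # matching pairs flagged stable
  expect_true(all(c("B1", "B2") %in% d$stable_pairs$module_a))

  # one 4-member module split into two equal halves: Jaccard 0.5 to each
  ba <- block_network(c(4L, 4L), rho = 0.8)
  half <- ba$assign
  half[c("t01", "t02")] <- "H1"; half[c("t03", "t04")] <- "H2"
  d2 <- differential_module_distance(ba$network, make_partition(ba$assign),
                                     ba$network, make_partition(half))
  expect_equal(d2$D["B1", "H1"], 0.5)
  expect_equal(d2$D["B1", "H2"], 0.5)

  # module pairs sharing no members sit at the maximum distance 1
  swapped <- stats::setNames(ifelse(ba$assign == "B1", "X2", "X1"),
                             names(ba$assign))
  d3 <- differential_module_distance(ba$network, make_partition(ba$assign),
                                     ba$network, make_partition(swapped))
  expect_equal(d3$D["B1", "X1"], 1)  # X1 holds B2's members
  expect_equal(d3$D["B2", "X2"], 1)
})

test_that("nmss is identically zero for a self-transition", {
  for (s in 1:5) {
    net <- random_network(15, 600 + s)
    part <- detect_modules(net, min_module_size = 3)
    d <- differential_module_distance(net, part, net, part)
    sc <- nmss(d)
    expect_true(all(sc$raw == 0))
    expect_true(all(sc$nmss == 0))
  }
})

test_that("nmss is equivariant under node relabeling", {
  x <- two_block_pair(move = "t02")
  d <- differential_module_distance(x$net_a, x$part_a, x$net_b, x$part_b)
  sc <- nmss(d)

  perm <- sample(10)
  pa <- correlation_network(x$net_a$adjacency[perm, perm])
  pb <- correlation_network(x$net_b$adjacency[perm, perm])
  ppa <- make_partition(x$part_a$modules[perm])
  ppb <- make_partition(x$part_b$modules[perm])
  d2 <- differential_module_distance(pa, ppa, pb, ppb)
  sc2 <- nmss(d2)
  expect_equal(sc2$nmss[match(sc$taxon, sc2$taxon)], sc$nmss)

  # single-node lookup and the rewired node ranking highest
  expect_equal(nmss(d, node = "t02"), 1)
  expect_error(nmss(d, node = "zz"), "unknown node")
})

test_that("a rewired driver ranks at the top of the scores", {
  hits <- 0L
  for (s in 1:5) {
    sim <- sim_two_arm(400 + s, n_taxa = 40L, n_per_arm = 60L,
                       module_sizes = c(8L, 8L), drivers = 2L,
                       effect = 1, rewire = TRUE)
    arms <- split_arms(sim)
    ch <- netshiftr:::nmss_chain(arms$control, arms$stress, seed = s)
    rk <- rank(-ch$scores$nmss)[ch$scores$taxon == "g002"]
    hits <- hits + (rk <= ceiling(0.05 * 40))
  }
  expect_gte(hits, 4L)
})

test_that("benjamini-hochberg adjustment matches the brute-force step-up", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               rep(0.03, 3))
  bh_bruteforce <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(9)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), bh_bruteforce(p))
  }
})

test_that("significance output is well-formed with non-zero p-values", {
  sim <- sim_two_arm(55, n_taxa = 12L, n_per_arm = 15L, module_sizes = c(4L),
                     drivers = 1L, effect = 1, depth = 5000L)
  arms <- split_arms(sim)
  res <- nmss_significance(NULL, arms$control, arms$stress,
                           n_permutations = 100L, seed = 5,
                           control = economy_control())
  expect_true(all(res$p_value > 0))
  expect_true(all(res$p_value <= 1 & res$q_value <= 1))
  expect_true(all(res$direction %in% c("enriched_in_A", "enriched_in_B", "none")))
  # q respects the BH relation to p
  expect_equal(res$q_value, stats::p.adjust(res$p_value, method = "BH"))
  expect_error(nmss_significance(NULL, arms$control, arms$stress,
                                 n_permutations = 50L), "100 permutations")
})

test_that("a single timepoint run reduces to one standard contrast", {
  sim <- sim_two_arm(66, n_taxa = 12L, n_per_arm = 15L, module_sizes = c(4L),
                     drivers = 1L, effect = 1, depth = 5000L,
                     n_timepoints = 1L)
  ctrl <- economy_control()
  per_tp <- run_per_timepoint(sim$table, sim$metadata, n_permutations = 100L,
                              seed = 77, control = ctrl)
  expect_length(per_tp, 1L)
  arms <- split_arms(sim)
  direct <- nmss_significance(NULL, arms$control, arms$stress,
                              n_permutations = 100L,
                              seed = derive_seed(77, "07_2022"),
                              control = ctrl)
  expect_equal(per_tp[["07_2022"]]$p_value, direct$p_value)
  expect_equal(per_tp[["07_2022"]]$nmss, direct$nmss)

  # determinism under a fixed seed
  again <- run_per_timepoint(sim$table, sim$metadata, n_permutations = 100L,
                             seed = 77, control = ctrl)
  expect_identical(per_tp[["07_2022"]], again[["07_2022"]])
})

test_that("a persistent rewired driver is significant in longitudinal mode", {
  sim <- sim_two_arm(501, n_timepoints = 3L)
  lg <- run_longitudinal(sim$table, sim$metadata, n_permutations = 150L,
                         seed = 19, control = economy_control())
  q_driver <- lg$q_value[lg$taxon %in% sim$truth$drivers]
  expect_true(all(q_driver < 0.05))
  expect_true(all(lg$p_value > 0))
})
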