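test_that("sparcc output is a valid correlation network on degenerate input", {
  set.seed(2)
  m <- matrix(rpois(15 * 6, 50), 15, 6,
              dimnames = list(sprintf("S%02d", 1:15), sprintf("t%02d", 1:6)))
  net <- sparcc(count_table(m), n_inner_iterations = 5, seed = 1)
  a <- net$adjacency
  expect_equal(a, t(a))
  expect_true(all(diag(a) == 1))
  expect_true(all(abs(a) <= 1))

  expect_error(sparcc(count_table(m[, 1:3])), ">= 4 taxa")
  expect_warning(sparcc(count_table(m[1:5, ]), n_inner_iterations = 2, seed = 1),
                 "fewer than 10 samples")
})

test_that("sparcc is exactly equivariant under taxon reordering", {
  set.seed(3)
  m <- matrix(rpois(30 * 8, 40), 30, 8,
              dimnames = list(sprintf("S%02d", 1:30), sprintf("t%02d", 1:8)))
  net1 <- sparcc(count_table(m), n_inner_iterations = 4, seed = 7)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  net2 <- sparcc(count_table(m[, perm]), n_inner_iterations = 4, seed = 7)
  expect_identical(net2$adjacency[colnames(m), colnames(m)], net1$adjacency)
})

test_that("sparcc recovers a planted pair and stays quiet on background", {
  sim <- sim_two_arm(17, n_taxa = 12L, n_per_arm = 400L, module_sizes = c(2L),
                     rho = 0.8, drivers = integer(0), effect = 0,
                     rewire = FALSE, depth = 10000L)
  arms <- split_arms(sim)
  net <- sparcc(arms$control, seed = 2)
  expect_lt(abs(net$adjacency["g001", "g002"] - 0.8), 0.15)
  rest <- net$adjacency
  rest[c("g001", "g002"), c("g001", "g002")] <- 0
  diag(rest) <- 0
  expect_lt(max(abs(rest)), 0.25)
})

test_that("network integration is a weighted edgewise mean", {
  a1 <- diag(1, 3); a1[1, 2] <- a1[2, 1] <- 0.2
  a2 <- diag(1, 3); a2[1, 2] <- a2[2, 1] <- 0.6
  dimnames(a1) <- dimnames(a2) <- list(letters[1:3], letters[1:3])
  n1 <- correlation_network(a1, condition = "control",
                            provenance = list(n_samples = 23))
  n2 <- correlation_network(a2, condition = "control",
                            provenance = list(n_samples = 23))

  # single network: identity; identical pair: idempotent
  expect_equal(integrate_networks(list(n1))$adjacency, a1)
  expect_equal(integrate_networks(list(n1, n1))$adjacency, a1)

  # equal weights -> arithmetic mean (0.4 for the 0.2/0.6 edge)
  mix <- integrate_networks(list(n1, n2))
  expect_equal(mix$adjacency["a", "b"], 0.4)

  # equal-weight integration equals the mean of adjacencies in general
  r1 <- random_network(6, 41); r2 <- random_network(6, 42)
  r1$provenance$n_samples <- r2$provenance$n_samples <- 30
  got <- integrate_networks(list(r1, r2))$adjacency
  expect_equal(got, (r1$adjacency + r2$adjacency) / 2)

  # explicit weights and union of taxa
  n3 <- correlation_network(diag(1, 2, 2) |>
                              `dimnames<-`(list(c("a", "d"), c("a", "d"))),
                            condition = "control")
  u <- integrate_networks(list(n1, n3), weights = c(1, 1))
  expect_identical(sort(u$taxon_ids), c("a", "b", "c", "d"))
  expect_equal(u$adjacency["b", "d"], 0)

  n_bad <- correlation_network(a2, condition = "stress")
  expect_error(integrate_networks(list(n1, n_bad)), "condition mismatch")
  expect_error(integrate_networks(list()), "empty")
})

test_that("topology metrics behave on known graphs", {
  # complete agreement: every degree n-1, density 1
  ones <- matrix(1, 10, 10)
  dimnames(ones) <- list(sprintf("t%02d", 1:10), sprintf("t%02d", 1:10))
  full <- topology(correlation_network(ones))
  expect_true(all(full$nodes$degree == 9))
  expect_equal(full$summary$density, 1)
  expect_equal(full$summary$mean_degree, 9)

  # threshold above the largest off-diagonal: empty graph
  weak <- random_network(8, 13, scale = 0.2)
  empty <- topology(weak, edge_threshold = 0.9)
  expect_true(all(empty$nodes$degree == 0))
  expect_equal(empty$summary$density, 0)

  # planted star: the hub holds all betweenness
  star <- diag(1, 7)
  star[1, 2:7] <- star[2:7, 1] <- 0.9
  dimnames(star) <- list(sprintf("t%d", 1:7), sprintf("t%d", 1:7))
  topo <- topology(correlation_network(star), edge_threshold = 0.3)
  expect_equal(which.max(topo$nodes$betweenness), 1L)
  expect_equal(topo$nodes$degree[1], 6)
  expect_true(all(topo$nodes$degree[-1] == 1))
})

test_that("degree is monotone non-increasing in the edge threshold", {
  net <- random_network(12, 31)
  prev <- rep(Inf, 12)
  for (thr in c(0.1, 0.3, 0.5, 0.7)) {
    deg <- topology(net, edge_threshold = thr)$nodes$degree
    expect_true(all(deg <= prev))
    prev <- deg
  }
})

test_that("topology comparison detects location shifts and flags mismatches", {
  net <- random_network(50, 77)
  rep_a <- topology(net)
  rep_b <- rep_a
  same <- compare_topology(rep_a, rep_b)
  expect_true(all(same$mean_difference == 0))
  expect_true(all(same$p_value > 0.9))

  rep_b$nodes$degree <- rep_b$nodes$degree + 5L
  shifted <- compare_topology(rep_b, rep_a)
  row <- shifted[shifted$metric == "degree", ]
  expect_equal(row$mean_difference, 5)
  expect_lt(row$p_value, 0.01)

  rep_c <- rep_a
  rep_c$nodes$strength <- NULL
  expect_warning(compare_topology(rep_a, rep_c), "strength")

  rep_d <- rep_a
  rep_d$nodes$node <- paste0("other_", rep_d$nodes$node)
  expect_error(compare_topology(rep_a, rep_d), "disjoint")
})
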