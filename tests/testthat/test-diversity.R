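test_that("shannon matches direct evaluation and its closed forms", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(10, 0, 0)), 0)
  p <- c(1, 2, 3) / 6
  expect_equal(shannon(c(1, 2, 3)), -sum(p * log(p)))
  expect_equal(shannon(c(1, 1), base = 2), 1)   # bits
  expect_error(shannon(c(0, 0)), "zero-sum")
})

test_that("alpha suite reproduces the estimator formulas", {
  # S_obs = 10, F1 = 2, F2 = 1 -> chao1 = 10 + 2*1/(2*(1+1)) = 10.5
  v <- c(1L, 1L, 2L, rep(5L, 7))
  tbl <- make_table(matrix(v, 1))
  a <- alpha_suite(tbl)
  expect_equal(a$observed, 10)
  expect_equal(a$chao1, 10.5)

  # no singletons -> chao1 equals observed richness
  b <- alpha_suite(make_table(matrix(rep(4L, 6), 1)))
  expect_equal(b$chao1, b$observed)
  expect_gte(b$ace, b$observed)

  expect_equal(alpha_suite(make_table(matrix(c(5L, 5L), 1)))$simpson, 0.5)
  expect_error(alpha_suite(make_table(matrix(c(1.5, 2), 1))), "integer")
})

test_that("alpha indices are invariant to taxon order", {
  set.seed(4)
  m <- matrix(rpois(40, 6), 4)
  a1 <- alpha_suite(make_table(m))
  perm <- sample(ncol(m))
  a2 <- alpha_suite(make_table(m[, perm], taxa = sprintf("t%02d", perm)))
  for (col in c("shannon", "simpson", "chao1", "ace")) {
    expect_equal(a1[[col]], a2[[col]])
  }
})

test_that("bray-curtis matches hand computation and its bounds", {
  tbl <- make_table(rbind(a = c(2L, 2L), b = c(2L, 0L), c = c(2L, 2L),
                          d = c(0L, 7L)),
                    samples = c("a", "b", "c", "d"))
  d <- bray_curtis(tbl)
  expect_equal(d["a", "c"], 0)                 # identical samples
  expect_equal(d["b", "d"], 1)                 # disjoint supports
  expect_equal(d["a", "b"], 1 / 3)             # 1 - 2*2/6
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("whittaker beta matches the gamma-over-mean-alpha form", {
  same <- make_table(rbind(c(1L, 2L, 3L), c(5L, 1L, 2L), c(2L, 2L, 2L)))
  expect_equal(whittaker_beta(same), 0)
  disjoint <- make_table(rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  expect_equal(whittaker_beta(disjoint), 1)
  # three samples of richness 4, pooled richness 6 -> 6/4 - 1 = 0.5
  m <- rbind(c(1L, 1L, 1L, 1L, 0L, 0L),
             c(0L, 1L, 1L, 1L, 1L, 0L),
             c(0L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(whittaker_beta(make_table(m)), 0.5)
  expect_equal(whittaker_beta(make_table(m), offset = FALSE), 1.5)
  expect_error(whittaker_beta(same, samples = "nope"), "unknown")
})

test_that("pcoa recovers known geometry", {
  # collinear points: one positive eigenvalue carries everything
  x <- c(0, 1, 3, 7)
  d_line <- as.matrix(stats::dist(cbind(x)))
  dimnames(d_line) <- list(sprintf("S%d", 1:4), sprintf("S%d", 1:4))
  fit <- suppressWarnings(pcoa_ordination(d_line, n_axes = 2))
  expect_lt(sum(abs(fit$eigenvalues[-1])), 1e-8)

  # planar points recovered up to rotation (Procrustes oracle)
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(stats::dist(pts))
  fit2 <- pcoa_ordination(d2, n_axes = 2)
  proc <- vegan::procrustes(pts, fit2$coordinates, symmetric = FALSE)
  expect_lt(proc$ss, 1e-8)

  # duplicate samples coincide in the embedding
  pts3 <- rbind(pts, pts[1, ])
  d3 <- as.matrix(stats::dist(pts3))
  fit3 <- pcoa_ordination(d3, n_axes = 2)
  expect_equal(fit3$coordinates[11, ], fit3$coordinates[1, ], tolerance = 1e-8)
})

test_that("permanova matches vegan::adonis2 and honors its conventions", {
  set.seed(12)
  m <- matrix(rpois(200, 20), 20)
  rownames(m) <- sprintf("S%02d", 1:20)
  colnames(m) <- sprintf("t%02d", 1:10)
  d <- bray_curtis(count_table(m))
  grp <- factor(rep(c("u", "v"), each = 10))
  mine <- permanova(d, grp, n_permutations = 199, seed = 3)
  ref <- vegan::adonis2(stats::as.dist(d) ~ grp, permutations = 199)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)

  # label invariance: permuting sample order leaves F unchanged
  perm <- sample(20)
  mine2 <- permanova(d[perm, perm], grp[perm], n_permutations = 99, seed = 3)
  expect_equal(mine2$pseudo_F, mine$pseudo_F)

  # perfectly separated duplicated groups: p attains the plus-one floor
  # (groups large enough that a permutation recreating the split is
  # vanishingly rare)
  base <- rbind(matrix(rep(c(10L, 0L, 0L, 2L), each = 8), 8),
                matrix(rep(c(0L, 9L, 5L, 0L), each = 8), 8))
  d2 <- bray_curtis(make_table(base))
  res <- permanova(d2, factor(rep(c("a", "b"), each = 8)),
                   n_permutations = 99, seed = 1)
  expect_equal(res$p_value, 1 / 100)
  expect_gt(res$p_value, 0)

  expect_error(permanova(d2, factor(rep("a", 16))), "2 groups")
})
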