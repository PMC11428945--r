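#' Shannon diversity of one sample
#'
#' \eqn{H = -\sum p_i \log p_i} over nonzero proportions, in natural log
#' units (nats) by default.
#'
#' @param counts_row non-negative numeric vector with positive sum.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index.
#' @export
shannon <- function(counts_row, base = exp(1)) {
  if (sum(counts_row) <= 0) stop_user("zero-sum sample")
  if (any(counts_row < 0)) stop_user("negative counts")
  p <- counts_row[counts_row > 0] / sum(counts_row)
  -sum(p * log(p, base = base))
}

#' Alpha-diversity suite per sample
#'
#' Shannon (nats), Simpson (`1 - sum p^2`), observed richness, and the
#' bias-corrected Chao1 and ACE richness estimators (integer counts
#' required; Chao1 uses `S_obs + F1(F1-1)/(2(F2+1))`, ACE uses the standard
#' rare/abundant split at 10). ACE is defined as observed richness when a
#' sample has no rare taxa.
#'
#' @param table a [count_table].
#' @param base logarithm base for Shannon.
#' @return data.frame with one row per sample: `sample_id`, `observed`,
#'   `shannon`, `simpson`, `chao1`, `ace`.
#' @export
alpha_suite <- function(table, base = exp(1)) {
  m <- table$counts
  if (any(m != round(m))) stop_user("Chao1/ACE require integer counts")
  if (any(rowSums(m) == 0)) stop_user("zero-sum sample(s) present")
  est <- vegan::estimateR(round(m))
  sh <- apply(m, 1L, shannon, base = base)
  simp <- apply(m, 1L, function(r) 1 - sum((r / sum(r))^2))
  obs <- est["S.obs", ]
  chao1 <- est["S.chao1", ]
  ace <- est["S.ACE", ]
  ace[!is.finite(ace)] <- obs[!is.finite(ace)]
  data.frame(sample_id = rownames(m), observed = unname(obs),
             shannon = unname(sh), simpson = unname(simp),
             chao1 = unname(chao1), ace = unname(ace),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis distance matrix
#'
#' \eqn{d(u, v) = 1 - 2\sum_i \min(u_i, v_i) / (\sum u + \sum v)}.
#'
#' @param table a [count_table] with at least 2 samples.
#' @return Square symmetric matrix with sample IDs, entries in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  m <- table$counts
  if (nrow(m) < 2) stop_user("need at least 2 samples")
  if (any(rowSums(m) == 0)) stop_user("zero-sum sample(s) present")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Whittaker beta diversity of a sample subset
#'
#' Species-turnover form \eqn{\beta_w = \gamma / \bar\alpha - 1}, where
#' \eqn{\gamma} is the pooled presence/absence richness of the subset and
#' \eqn{\bar\alpha} the mean per-sample richness; 0 when all samples share
#' one composition. Set `offset = FALSE` for the \eqn{\gamma/\bar\alpha}
#' form.
#'
#' @param table a [count_table].
#' @param samples optional character vector of sample IDs (default: all).
#' @param offset subtract 1 (default `TRUE`).
#' @return Whittaker beta value.
#' @export
whittaker_beta <- function(table, samples = NULL, offset = TRUE) {
  m <- table$counts
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(m))
    if (length(missing)) stop_user("unknown sample(s): ", paste(missing, collapse = ", "))
    m <- m[samples, , drop = FALSE]
  }
  if (nrow(m) == 0) stop_user("empty sample subset")
  pa <- m > 0
  gamma <- sum(colSums(pa) > 0)
  alpha_bar <- mean(rowSums(pa))
  if (alpha_bar == 0) stop_user("subset has no observed taxa")
  gamma / alpha_bar - if (offset) 1 else 0
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower-centered double-centering of \eqn{-\tfrac12 d^2}; axes are limited
#' to positive eigenvalues, negative eigenvalues are reported, and each
#' axis' sign is fixed so its first nonzero loading is positive.
#'
#' @param dist square symmetric distance matrix.
#' @param n_axes number of axes requested (default 2); truncated with a
#'   warning if it exceeds the number of positive eigenvalues.
#' @return list(coordinates, eigenvalues, proportion_explained).
#' @export
pcoa_ordination <- function(dist, n_axes = 2L) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop_user("distance matrix must be symmetric")
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; we inspect
  # and report the spectrum ourselves
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-9 & eig > 0)
  if (n_axes > length(pos)) {
    warning(sprintf("requested %d axes but only %d positive eigenvalues; truncating",
                    n_axes, length(pos)))
    n_axes <- length(pos)
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- sprintf("PCo%d", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = pmax(eig, 0) / sum(pmax(eig, 0)))
}

#' Distance-based PERMANOVA (one factor)
#'
#' Pseudo-F from the distance-based partition of sums of squares
#' (Gower-centered), with a label-permutation null and the plus-one p-value
#' convention \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + P)}, so p is
#' never exactly 0.
#'
#' @param dist square symmetric distance matrix (samples in rows/cols).
#' @param labels factor of group labels, aligned with `dist`; at least 2
#'   groups of at least 2 samples each.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return list(pseudo_F, R2, p_value, n_permutations).
#' @export
permanova <- function(dist, labels, n_permutations = 999L, seed = NULL) {
  d <- as.matrix(dist)
  labels <- droplevels(factor(labels))
  if (length(labels) != nrow(d)) stop_user("labels length must match distance matrix")
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop_user("need >= 2 groups with >= 2 samples each")
  }
  n <- nrow(d)
  a <- length(sizes)
  D2 <- d^2
  sst <- sum(D2) / (2 * n)
  ssw_of <- function(lab) {
    s <- 0
    for (g in levels(lab)) {
      idx <- lab == g
      s <- s + sum(D2[idx, idx]) / (2 * sum(idx))
    }
    s
  }
  ssw <- ssw_of(labels)
  ssa <- sst - ssw
  f_obs <- (ssa / (a - 1)) / (ssw / (n - a))
  r2 <- ssa / sst
  with_seed(seed, {
    f_perm <- vapply(seq_len(n_permutations), function(i) {
      lab <- labels[sample.int(n)]
      sw <- ssw_of(lab)
      ((sst - sw) / (a - 1)) / (sw / (n - a))
    }, numeric(1))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
    list(pseudo_F = f_obs, R2 = r2, p_value = p,
         n_permutations = as.integer(n_permutations))
  })
}
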