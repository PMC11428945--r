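#' Construct a correlation network
#'
#' @param adjacency symmetric numeric matrix in \[-1, 1\] with unit
#'   diagonal; dimnames are taxon IDs.
#' @param condition optional condition label (`"control"` or `"stress"`).
#' @param provenance list of free-form provenance entries (contributing
#'   timepoints, parameters, sample sizes).
#' @return An object of class `correlation_network`.
#' @export
correlation_network <- function(adjacency, condition = NULL, provenance = list()) {
  a <- as.matrix(adjacency)
  if (is.null(rownames(a))) {
    rownames(a) <- colnames(a) <- sprintf("t%d", seq_len(nrow(a)))
  }
  if (!isSymmetric(unname(a), tol = 1e-8)) stop_user("adjacency must be symmetric")
  a <- (a + t(a)) / 2
  if (any(abs(a) > 1 + 1e-8)) stop_user("adjacency entries must lie in [-1, 1]")
  a <- pmin(pmax(a, -1), 1)
  diag(a) <- 1
  structure(list(adjacency = a, taxon_ids = rownames(a),
                 condition = condition, provenance = provenance),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d taxa%s\n", length(x$taxon_ids),
              if (!is.null(x$condition)) paste0(" (", x$condition, ")") else ""))
  invisible(x)
}

# Solve basis variances from the variation matrix under the sparsity
# approximation, honoring pairwise exclusions.
# T_mat: variation matrix t_ij = var(log(x_i/x_j)); allowed: logical matrix
# of non-excluded pairs (diag FALSE).
solve_basis_variances <- function(T_mat, allowed) {
  M <- allowed * 1
  diag(M) <- rowSums(allowed)
  t_vec <- rowSums(T_mat * allowed)
  omega2 <- tryCatch(solve(M, t_vec), error = function(e)
    stop_user("singular basis-variance system after pair exclusions; ",
              "try fewer exclusion rounds"))
  pmax(omega2, 1e-12)
}

# Vectorized per-row median (single order() call instead of one sort per row)
row_medians <- function(X) {
  k <- ncol(X)
  if (k == 1L) return(X[, 1L])
  S <- matrix(X[order(row(X), X)], nrow(X), k, byrow = TRUE)
  if (k %% 2L == 1L) S[, (k + 1L) %/% 2L] else (S[, k %/% 2L] + S[, k %/% 2L + 1L]) / 2
}

basis_correlation_once <- function(T_mat, exclusion_threshold, n_exclusion_rounds) {
  D <- nrow(T_mat)
  allowed <- matrix(TRUE, D, D)
  diag(allowed) <- FALSE
  rho <- NULL
  for (round in seq_len(n_exclusion_rounds + 1L)) {
    omega2 <- solve_basis_variances(T_mat, allowed)
    denom <- 2 * sqrt(omega2 %o% omega2)
    rho <- (outer(omega2, omega2, `+`) - T_mat) / denom
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (round > n_exclusion_rounds) break
    cand <- abs(rho)
    cand[!allowed] <- -Inf
    # never exclude a pair that would leave a taxon with < 2 partners
    # (keeps the basis-variance system nonsingular)
    deg <- rowSums(allowed)
    cand[deg <= 2, ] <- -Inf
    cand[, deg <= 2] <- -Inf
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1L, ]
    allowed[ij[1L], ij[2L]] <- allowed[ij[2L], ij[1L]] <- FALSE
  }
  rho
}

#' SparCC basis correlations from compositional counts
#'
#' Iterative estimation of latent ("basis") correlations from count
#' compositions: per inner iteration, taxon fractions are drawn from a
#' Dirichlet posterior (counts + pseudocount), the log-ratio variation
#' matrix \eqn{t_{ij} = var(\log(x_i/x_j))} is formed, basis variances are
#' solved under the sparsity approximation, and the most strongly
#' correlated pairs are iteratively excluded from the system (up to
#' `n_exclusion_rounds`, while the strongest |correlation| exceeds
#' `exclusion_threshold`). The final adjacency is the entrywise median over
#' inner iterations, clipped to \[-1, 1\].
#'
#' @param table a [count_table] with >= 4 taxa (the basis-variance linear
#'   system is underdetermined below that); a warning is issued below 10
#'   samples.
#' @param n_inner_iterations Dirichlet resampling iterations (default 20).
#' @param exclusion_threshold strongest-pair exclusion threshold
#'   (default 0.1).
#' @param n_exclusion_rounds maximum excluded pairs per iteration
#'   (default 10).
#' @param pseudocount Dirichlet prior pseudocount (default 0.5).
#' @param seed integer seed.
#' @param condition optional condition label stored on the network.
#' @return A [correlation_network].
#' @export
sparcc <- function(table, n_inner_iterations = 20L, exclusion_threshold = 0.1,
                   n_exclusion_rounds = 10L, pseudocount = 0.5, seed = NULL,
                   condition = NULL) {
  m <- table$counts
  D <- ncol(m)
  n <- nrow(m)
  if (D < 4L) stop_user("SparCC requires >= 4 taxa (linear system underdetermined)")
  if (n < 10L) warning("SparCC with fewer than 10 samples is unreliable")
  # work in sorted taxon order so the estimate is exactly equivariant under
  # permutation of the input columns (RNG draws then align per taxon)
  ord <- order(colnames(m))
  inv <- match(colnames(m), colnames(m)[ord])
  m <- m[, ord, drop = FALSE]
  with_seed(seed, {
    acc <- array(NA_real_, dim = c(D, D, n_inner_iterations))
    for (it in seq_len(n_inner_iterations)) {
      # Dirichlet posterior draw of fractions, per sample
      g <- matrix(stats::rgamma(n * D, shape = as.vector(m) + pseudocount),
                  nrow = n, ncol = D)
      f <- g / rowSums(g)
      L <- log(f)
      V <- stats::cov(L)
      v <- diag(V)
      T_mat <- outer(v, v, `+`) - 2 * V
      diag(T_mat) <- 0
      acc[, , it] <- basis_correlation_once(T_mat, exclusion_threshold,
                                            n_exclusion_rounds)
    }
    a <- matrix(row_medians(matrix(acc, D * D, n_inner_iterations)), D, D)
    dimnames(a) <- list(colnames(m), colnames(m))
    a <- a[inv, inv, drop = FALSE]
    correlation_network(a, condition = condition,
                        provenance = list(method = "sparcc",
                                          n_samples = n,
                                          n_inner_iterations = n_inner_iterations,
                                          exclusion_threshold = exclusion_threshold,
                                          n_exclusion_rounds = n_exclusion_rounds,
                                          pseudocount = pseudocount))
  })
}
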