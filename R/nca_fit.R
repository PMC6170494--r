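# Fixed-support network component analysis: the residual
#   q(G) = min_{S in G, A} ||E - S A||_F^2
# where "S in G" pins the non-zero pattern of S to the support G. Solved by
# alternating least squares; each half step is an exact partial minimum so
# the residual can only decrease.

#' Fixed-support NCA residual q(G)
#'
#' Measures how well a network topology explains expression data: the
#' minimal squared Frobenius residual of the linear activity model when the
#' support of the regulatory-potential matrix is fixed to the given
#' network. The A-step solves unconstrained least squares via the
#' pseudoinverse; the S-step solves, per gene, a least-squares fit over
#' only that gene's regulators (minimum-norm when rank-deficient, so
#' degenerate supports do not crash). A gene with no regulators contributes
#' `||E(i,)||^2` to q, making q comparable across cutoff networks.
#'
#' The problem is nonconvex, so ALS from a random start can stall in a
#' local minimum; `n_restarts > 1` reruns the fit from independently
#' seeded starts and keeps the best residual (standard multistart).
#'
#' @param expr an [expression_matrix()].
#' @param support a [grn_edge_set()]; only the non-zero pattern is used.
#' @param max_iter maximum ALS sweeps.
#' @param tol relative residual-change tolerance.
#' @param seed seed for the standard-normal initialization of S.
#' @param n_restarts number of multistart repetitions (best q kept).
#' @return list with `q` (the residual), `q_normalized` (`q / ||E||_F^2`),
#'   `S` (a [grn_edge_set()]), `A` (an [activity_matrix()]), and `sweeps`.
#' @export
nca_residual <- function(expr, support, max_iter = 200L, tol = 1e-8,
                         seed = 1L, n_restarts = 1L) {
  stopifnot(n_restarts >= 1)
  if (n_restarts > 1L) {
    fits <- lapply(seq_len(n_restarts), function(r) {
      nca_residual(expr, support, max_iter = max_iter, tol = tol,
                   seed = derive_seed(seed, r), n_restarts = 1L)
    })
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "q"))]])
  }
  E <- expr$values
  N <- nrow(E)
  tf_ids <- support$tf_ids
  M <- length(tf_ids)
  normE2 <- sum(E^2)
  if (n_edges(support) == 0L || M == 0L) {
    return(list(q = normE2, q_normalized = 1,
                S = support,
                A = activity_matrix(matrix(0, M, ncol(E)), tf_ids,
                                    expr$sample_ids),
                sweeps = 0L))
  }
  mask <- as.matrix(sparsify(support, gene_ids = expr$gene_ids,
                             tf_ids = tf_ids)) != 0
  regulators <- apply(mask, 1, which, simplify = FALSE)
  S <- matrix(0, N, M)
  S[mask] <- with_seed(seed, stats::rnorm(sum(mask)))
  q_prev <- Inf
  sweeps <- 0L
  for (sweep in seq_len(max_iter)) {
    A <- pinv_solve(S, E)
    for (i in seq_len(N)) {
      J <- regulators[[i]]
      if (length(J) == 0L) next
      S[i, J] <- lstsq_min_norm(t(A[J, , drop = FALSE]), E[i, ])
    }
    q <- sum((E - S %*% A)^2)
    if (q > q_prev * (1 + 1e-9) + 1e-12) {
      stop(sprintf("NCA residual increased across an ALS sweep (%.6g -> %.6g)",
                   q_prev, q))
    }
    sweeps <- sweep
    if (is.finite(q_prev) &&
        (q_prev - q) <= tol * max(q_prev, 1e-30)) {
      q_prev <- q
      break
    }
    q_prev <- q
  }
  rownames(S) <- expr$gene_ids; colnames(S) <- tf_ids
  list(q = q_prev, q_normalized = q_prev / normE2,
       S = densify(S, gene_ids = expr$gene_ids, tf_ids = tf_ids),
       A = activity_matrix(A, tf_ids, expr$sample_ids),
       sweeps = sweeps)
}
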