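# The reprogramming objective and its PALM solver.
#
# The model: expression E (genes x samples) is approximated by S %*% A where
# S is a sparse genes x TFs matrix of regulatory potentials and A the latent
# TF activity matrix. The objective is
#
#   1/2 ||E - SA||_F^2
#   + lambda * (#prior edges removed + #edges added beyond the prior)
#   + kappa  * tr(S' L S)          (coexpression graph embedding)
#   + eta    * ||S||_0             (l0 elastic net, sparsity)
#   + xi     * ||S||_F^2           (l0 elastic net, grouping)
#   + mu     * ||A||_F^2           (activity smoothness)
#   s.t. ||S||_inf <= a, ||A||_inf <= b
#
# solved by proximal alternating linearized minimization: block gradient
# steps with step sizes bounded by the block Lipschitz constants, followed
# by exact proximal maps (clipping for A, a weighted-l0 box prox for S).
# Each iteration provably does not increase the objective.

#' Build a coexpression graph Laplacian
#'
#' Constructs a sparse gene-gene affinity graph from absolute Pearson
#' correlation: gene pairs are connected when one is among the other's
#' `knn_k` most correlated partners and `|r| >= tau`; weights are `|r|`,
#' symmetrized by the elementwise maximum. Returns the graph weights and
#' the combinatorial Laplacian `L = D - W` used by the embedding penalty.
#'
#' @param expr an [expression_matrix()] with at least 3 samples.
#' @param method affinity; only `"abs_pearson"` is implemented.
#' @param knn_k number of nearest neighbours retained per gene.
#' @param tau hard threshold on `|r|` in `[0, 1]`.
#' @return list of class `coexpression_laplacian` with sparse `W`
#'   (symmetric, zero diagonal, entries in `[0, 1]`) and `L_mat = D - W`.
#' @export
build_coexpression_laplacian <- function(expr, method = "abs_pearson",
                                         knn_k = 10L, tau = 0.5) {
  method <- match.arg(method, "abs_pearson")
  stopifnot(tau >= 0, tau <= 1, knn_k >= 1)
  v <- expr$values
  if (ncol(v) < 3L) stop("need at least 3 samples for correlations")
  n <- nrow(v)
  sds <- apply(v, 1, stats::sd)
  const <- sds < 1e-12
  if (any(const)) {
    warning(sum(const), " constant gene row(s); their correlations set to 0")
  }
  R <- suppressWarnings(abs(stats::cor(t(v))))
  R[!is.finite(R)] <- 0
  R[const, ] <- 0
  R[, const] <- 0
  diag(R) <- 0
  # keep, per row, the knn_k largest |r| that also pass tau
  keep <- matrix(FALSE, n, n)
  k <- min(knn_k, n - 1L)
  for (i in seq_len(n)) {
    ord <- order(R[i, ], decreasing = TRUE)[seq_len(k)]
    ok <- ord[R[i, ord] >= tau & R[i, ord] > 0]
    keep[i, ok] <- TRUE
  }
  keep <- keep | t(keep)  # symmetrize by max: |r| is already symmetric
  W <- Matrix::Matrix(ifelse(keep, R, 0), sparse = TRUE)
  d <- Matrix::rowSums(W)
  L_mat <- Matrix::Diagonal(n, d) - W
  structure(list(W = W, L_mat = L_mat, gene_ids = expr$gene_ids),
            class = "coexpression_laplacian")
}

#' @export
print.coexpression_laplacian <- function(x, ...) {
  cat(sprintf("<coexpression_laplacian: %d genes, %d edges>\n",
              nrow(x$W), Matrix::nnzero(x$W) / 2))
  invisible(x)
}

# Edge-change + l0 cost of a candidate S given prior support masks.
# on_prior / off_prior: logical matrices; S: dense matrix.
edge_penalty_terms <- function(S, on_prior, lambda, eta) {
  nz <- S != 0
  removed <- sum(on_prior & !nz)
  added <- sum(!on_prior & nz)
  lambda * (removed + added) + eta * sum(nz)
}

#' Evaluate the reprogramming objective
#'
#' Computes the full penalized objective at a candidate `(S, A)` pair.
#' Primarily a diagnostic and testing entry point; the solver tracks the
#' same quantity internally.
#'
#' @param expr an [expression_matrix()] (already preprocessed).
#' @param S genes x TFs regulatory-potential matrix (dense or sparse).
#' @param A TFs x samples activity matrix.
#' @param prior the prior [grn_edge_set()] defining the support masks.
#' @param lap a [build_coexpression_laplacian()] result.
#' @param params a [netrex_params()]; `b = NULL` resolves to `max(abs(E))`.
#' @return scalar objective value.
#' @export
netrex_objective <- function(expr, S, A, prior, lap, params) {
  E <- expr$values
  S <- as.matrix(S)
  A <- as.matrix(A)
  b <- if (is.null(params$b)) max(abs(E)) else params$b
  if (max(abs(S)) > params$a + 1e-12) stop("||S||_inf exceeds box bound a")
  if (max(abs(A)) > b + 1e-12) stop("||A||_inf exceeds box bound b")
  S0 <- as.matrix(sparsify(prior, gene_ids = expr$gene_ids))
  on_prior <- S0 != 0
  R <- E - S %*% A
  0.5 * sum(R^2) +
    edge_penalty_terms(S, on_prior, params$lambda, params$eta) +
    params$kappa * sum(S * as.matrix(lap$L_mat %*% S)) +
    params$xi * sum(S^2) +
    params$mu * sum(A^2)
}

#' Weighted-l0 box proximal operator
#'
#' Solves, entrywise and exactly,
#' \deqn{\arg\min_x \frac{1}{2\,step}(x-v)^2 + c_{nz}\,1[x \ne 0] +
#'       c_z\,1[x = 0] \quad s.t.\ |x| \le a.}
#' The only candidate minimizers are `x = 0` and `x = clip(v, [-a, a])`;
#' the cheaper wins and an exact tie yields 0 (the sparser choice).
#' All arguments are vectorized.
#'
#' @param v proposal value(s) (the gradient-step result).
#' @param step positive step size(s).
#' @param cost_nonzero,cost_zero non-negative costs for keeping/zeroing.
#' @param a positive box bound.
#' @return the prox result, same shape as `v`.
#' @export
prox_weighted_l0_box <- function(v, step, cost_nonzero, cost_zero, a) {
  xc <- pmin(pmax(v, -a), a)
  cost_keep <- (xc - v)^2 / (2 * step) + cost_nonzero
  cost_drop <- v^2 / (2 * step) + cost_zero
  ifelse(cost_keep < cost_drop, xc, 0)
}

#' Reprogram a prior network with PALM
#'
#' Alternating block updates: a gradient step on the activities followed by
#' clipping to `[-b, b]`, then a gradient step on the regulatory potentials
#' followed by the weighted-l0 box prox ([prox_weighted_l0_box()]) with
#' per-entry costs `(eta, lambda)` on prior-supported entries and
#' `(lambda + eta, 0)` elsewhere. Step sizes are `1/(gamma * c)` with `c`
#' the block Lipschitz bound (spectral norms by power iteration) and
#' `gamma = 1.1`, so the objective never increases. Terminates when the
#' relative objective change drops below `params$tol` or after
#' `params$max_iter` iterations.
#'
#' @param expr an [expression_matrix()] (preprocess first; see
#'   [preprocess_expression()]).
#' @param prior a non-empty prior [grn_edge_set()]; its TF list defines the
#'   TF universe.
#' @param lap a [build_coexpression_laplacian()] built on `expr` (or `NULL`
#'   to build one with defaults).
#' @param params a [netrex_params()].
#' @param init `"prior_ls"` (start at the prior, activities by least
#'   squares) or `"given"` (supply `S_init`, `A_init`).
#' @param S_init,A_init optional starting matrices for `init = "given"`.
#' @return list with `S` (a [grn_edge_set()] of the retained weighted
#'   edges), `A` (an [activity_matrix()]), and `trace` (class
#'   `solver_trace`: per-iteration objectives, convergence flag, and
#'   `edge_change_counts` relative to the prior).
#' @export
palm_solve <- function(expr, prior, lap = NULL, params = netrex_params(),
                       init = c("prior_ls", "given"),
                       S_init = NULL, A_init = NULL) {
  init <- match.arg(init)
  if (n_edges(prior) == 0L) stop("prior network is empty")
  E <- expr$values
  N <- nrow(E); Ls <- ncol(E)
  gene_ids <- expr$gene_ids
  tf_ids <- prior$tf_ids
  M <- length(tf_ids)
  if (is.null(lap)) lap <- build_coexpression_laplacian(expr)
  L_mat <- lap$L_mat
  a <- params$a
  b <- if (is.null(params$b)) max(abs(E)) else params$b
  lambda <- params$lambda; kappa <- params$kappa; eta <- params$eta
  xi <- params$xi; mu <- params$mu
  gamma <- 1.1
  eps <- 1e-12

  S0 <- as.matrix(sparsify(prior, gene_ids = gene_ids, tf_ids = tf_ids))
  on_prior <- S0 != 0
  # per-entry prox costs realizing the lambda/eta terms
  c_nz <- ifelse(on_prior, eta, lambda + eta)
  c_z <- ifelse(on_prior, lambda, 0)

  if (init == "prior_ls") {
    S <- S0
    if (all(abs(S[on_prior] - 1) < 1e-12)) S[on_prior] <- 0.5 * a
    S <- pmin(pmax(S, -a), a)
    A <- pinv_solve(S, E)
    A <- pmin(pmax(A, -b), b)
  } else {
    if (is.null(S_init) || is.null(A_init)) {
      stop("init = 'given' requires S_init and A_init")
    }
    S <- pmin(pmax(as.matrix(S_init), -a), a)
    A <- pmin(pmax(as.matrix(A_init), -b), b)
  }

  sigma_L <- if (kappa > 0) power_sigma_max(L_mat) else 0

  objective <- function(S, A, SA) {
    val <- 0.5 * sum((E - SA)^2) +
      edge_penalty_terms(S, on_prior, lambda, eta) +
      xi * sum(S^2) + mu * sum(A^2)
    if (kappa > 0) val <- val + kappa * sum(S * as.matrix(L_mat %*% S))
    val
  }

  SA <- S %*% A
  obj <- objective(S, A, SA)
  if (!is.finite(obj)) stop("non-finite objective at initialization")
  trace_obj <- numeric(params$max_iter + 1L)
  trace_obj[1] <- obj
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(params$max_iter)) {
    # A-block: gradient S'(SA - E) + 2 mu A, Lipschitz sigma_max(S'S) + 2 mu
    StS <- crossprod(S)
    c_A <- max(power_sigma_max(StS) + 2 * mu, eps)
    G_A <- crossprod(S, SA - E) + 2 * mu * A
    A <- A - G_A / (gamma * c_A)
    A <- pmin(pmax(A, -b), b)
    SA <- S %*% A

    # S-block: gradient (SA - E)A' + 2 kappa L S + 2 xi S
    AAt <- tcrossprod(A)
    c_S <- max(power_sigma_max(AAt) + 2 * kappa * sigma_L + 2 * xi, eps)
    step <- 1 / (gamma * c_S)
    G_S <- tcrossprod(SA - E, A) + 2 * xi * S
    if (kappa > 0) G_S <- G_S + 2 * kappa * as.matrix(L_mat %*% S)
    V <- S - step * G_S
    S <- prox_weighted_l0_box(V, step, c_nz, c_z, a)
    SA <- S %*% A

    obj_new <- objective(S, A, SA)
    if (!is.finite(obj_new)) stop("non-finite objective during solve")
    if (obj_new > obj + 1e-9) {
      stop(sprintf("objective increased at iteration %d (%.3e -> %.3e)",
                   iter, obj, obj_new))
    }
    trace_obj[iter + 1L] <- obj_new
    rel <- abs(obj - obj_new) / max(abs(obj), 1e-30)
    obj <- obj_new
    if (rel < params$tol) {
      converged <- TRUE
      break
    }
  }

  nz <- S != 0
  removed <- sum(on_prior & !nz)
  added <- sum(!on_prior & nz)
  trace <- structure(
    list(objective = trace_obj[seq_len(iter + 1L)],
         iterations_run = iter, converged = converged,
         edge_change_counts = c(removed_from_prior = removed,
                                added_beyond_prior = added)),
    class = "solver_trace")

  rownames(S) <- gene_ids; colnames(S) <- tf_ids
  list(S = densify(S, gene_ids = gene_ids, tf_ids = tf_ids),
       A = activity_matrix(A, tf_ids, expr$sample_ids),
       trace = trace)
}

#' @export
print.solver_trace <- function(x, ...) {
  cat(sprintf(
    "<solver_trace: %d iterations, %s, objective %.6g -> %.6g, -%d/+%d edges>\n",
    x$iterations_run, if (x$converged) "converged" else "max_iter reached",
    x$objective[1], x$objective[length(x$objective)],
    x$edge_change_counts[["removed_from_prior"]],
    x$edge_change_counts[["added_beyond_prior"]]))
  invisible(x)
}
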