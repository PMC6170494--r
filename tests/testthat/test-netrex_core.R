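test_that("coexpression Laplacian handles perfect and absent correlation", {
  vals <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  expr <- expression_matrix(vals, c("g1", "g2", "g3"), paste0("s", 1:4))
  lap <- build_coexpression_laplacian(expr, knn_k = 2, tau = 0)
  W <- as.matrix(lap$W)
  expect_equal(W[1, 2], 1)          # identical direction, |r| = 1
  expect_equal(diag(W), rep(0, 3), ignore_attr = TRUE)
  expect_equal(unname(Matrix::rowSums(lap$L_mat)), rep(0, 3), tolerance = 1e-9)

  # orthogonal-ish rows below the threshold give an empty graph
  v2 <- rbind(c(1, -1, 1, -1, 1, -1), c(1, 1, -1, -1, 1, 1) * 0.98 +
                c(0.01, -0.02, 0.03, 0, 0, -0.01))
  e2 <- expression_matrix(rbind(v2, c(0.5, 0.1, -0.3, 0.2, -0.4, 0.15)),
                          c("a", "b", "c"), paste0("s", 1:6))
  lap2 <- build_coexpression_laplacian(e2, knn_k = 2, tau = 0.99)
  expect_equal(Matrix::nnzero(lap2$W), 0)
})

test_that("Laplacian quadratic form equals the pairwise-difference sum", {
  expr <- tiny_expr(10, 20, seed = 7)
  lap <- build_coexpression_laplacian(expr, knn_k = 4, tau = 0.1)
  W <- as.matrix(lap$W)
  L <- as.matrix(lap$L_mat)
  withr::with_seed(11, {
    for (rep in 1:100) {
      x <- rnorm(10)
      direct <- 0.5 * sum(W * outer(x, x, function(a, b) (a - b)^2))
      expect_equal(as.numeric(t(x) %*% L %*% x), direct, tolerance = 1e-8)
    }
  })
})

test_that("constant gene rows are flagged and given zero correlation", {
  vals <- rbind(rep(1, 5), rnorm(5), rnorm(5))
  expr <- expression_matrix(vals, c("flat", "g2", "g3"), paste0("s", 1:5))
  expect_warning(lap <- build_coexpression_laplacian(expr, knn_k = 2, tau = 0),
                 "constant")
  expect_equal(sum(as.matrix(lap$W)[1, ]), 0)
})

test_that("objective matches closed forms in degenerate corners", {
  sim <- tiny_instance(n_genes = 6, n_tfs = 3, n_samples = 5, n_edges = 9,
                       noise_sd = 0.2, seed = 2)
  expr <- sim$expr
  prior <- sim$S_true
  lap <- build_coexpression_laplacian(expr, knn_k = 3, tau = 0)
  p <- netrex_params(lambda = 0.7, kappa = 0.3, eta = 0.2, xi = 0.4, mu = 0.9,
                     a = 2, b = 10)
  S0 <- as.matrix(sparsify(prior, gene_ids = expr$gene_ids))
  A0 <- matrix(0, 3, 5)

  # A = 0 removes the SA product and the mu term; no edge changes
  obj <- netrex_objective(expr, S0, A0, prior, lap, p)
  expected <- 0.5 * sum(expr$values^2) +
    p$kappa * sum(diag(t(S0) %*% as.matrix(lap$L_mat) %*% S0)) +
    p$eta * sum(S0 != 0) + p$xi * sum(S0^2)
  expect_equal(obj, expected, tolerance = 1e-10)

  # S = 0: every prior edge counts as removed
  obj0 <- netrex_objective(expr, S0 * 0, A0, prior, lap, p)
  expect_equal(obj0, 0.5 * sum(expr$values^2) + p$lambda * sum(S0 != 0),
               tolerance = 1e-10)
})

test_that("objective equals independent term-wise recomputation", {
  sim <- tiny_instance(n_genes = 6, n_tfs = 3, n_samples = 5, n_edges = 10,
                       noise_sd = 0.3, seed = 5)
  lap <- build_coexpression_laplacian(sim$expr, knn_k = 3, tau = 0)
  p <- netrex_params(lambda = 0.3, kappa = 0.15, eta = 0.25, xi = 0.05,
                     mu = 0.4, a = 3, b = 20)
  S0 <- as.matrix(sparsify(sim$S_true, gene_ids = sim$expr$gene_ids))
  withr::with_seed(8, {
    S <- S0 * matrix(rbinom(length(S0), 1, 0.8), nrow(S0)) +
      matrix(rbinom(length(S0), 1, 0.1) * runif(length(S0), -1, 1), nrow(S0))
    S <- pmin(pmax(S, -3), 3)
    A <- matrix(runif(15, -2, 2), 3, 5)
  })
  expect_equal(netrex_objective(sim$expr, S, A, sim$S_true, lap, p),
               naive_objective(sim$expr$values, S, A, S0, lap$L_mat,
                               p$lambda, p$kappa, p$eta, p$xi, p$mu),
               tolerance = 1e-10)
})

test_that("weighted-l0 box prox picks the cheaper of zero and clip", {
  expect_equal(prox_weighted_l0_box(0, 1, 0.3, 0.1, 1), 0)
  # no l0 costs: pure clipping
  expect_equal(prox_weighted_l0_box(3, 0.5, 0, 0, 2), 2)
  expect_equal(prox_weighted_l0_box(-3, 0.5, 0, 0, 2), -2)
  # worked example: keep-cost 0.8 beats drop-cost 1.0, then loses at 1.2
  expect_equal(prox_weighted_l0_box(1.0, 0.5, 0.8, 0, 2), 1.0)
  expect_equal(prox_weighted_l0_box(1.0, 0.5, 1.2, 0, 2), 0)
  # exact tie goes to zero (sparser)
  expect_equal(prox_weighted_l0_box(1.0, 0.5, 1.0, 0, 2), 0)
  # vectorized over proposals
  expect_equal(prox_weighted_l0_box(c(0, 3, 1), 0.5, c(0.3, 0, 1.2),
                                    c(0, 0, 0), 2),
               c(0, 2, 0))
})

test_that("solver reproduces a noise-free instance from a perfect prior", {
  sim <- tiny_instance(n_genes = 30, n_tfs = 3, n_samples = 15, n_edges = 60,
                       noise_sd = 0, seed = 4)
  ex <- preprocess_expression(sim$expr, "center-genes")
  lap <- build_coexpression_laplacian(ex, knn_k = 5, tau = 0.3)
  p <- netrex_params(lambda = 1e6, kappa = 0, eta = 0.001, xi = 1e-6,
                     mu = 1e-6, max_iter = 3000, tol = 1e-12)
  fit <- palm_solve(ex, sim$S_true, lap, p)
  # huge change penalty: support must equal the prior support exactly
  expect_equal(fit$trace$edge_change_counts,
               c(removed_from_prior = 0, added_beyond_prior = 0))
  resid <- sum((ex$values - as.matrix(sparsify(fit$S, ex$gene_ids)) %*%
                  fit$A$values)^2)
  expect_lt(resid, 1e-6 * sum(ex$values^2))
})

test_that("solver trace is monotone and feasible at every exit", {
  sim <- tiny_instance(n_genes = 25, n_tfs = 4, n_samples = 12, n_edges = 50,
                       noise_sd = 0.3, seed = 9)
  prior <- corrupt_prior_fixed_total(sim$S_true, 0.6, seed = 2)
  ex <- preprocess_expression(sim$expr)
  lap <- build_coexpression_laplacian(ex, knn_k = 5, tau = 0.3)
  p <- netrex_params(lambda = 1, eta = 0.3, a = 0.8, b = 2.5)
  fit <- palm_solve(ex, prior, lap, p)
  expect_true(all(diff(fit$trace$objective) <= 1e-9))
  expect_lte(max(abs(fit$S$edges$weight)), 0.8)
  expect_lte(max(abs(fit$A$values)), 2.5)
  # support arithmetic: |S union S0| consistent with added/removed counts
  s_keys <- paste(fit$S$edges$tf, fit$S$edges$gene)
  p_keys <- paste(prior$edges$tf, prior$edges$gene)
  u <- length(union(s_keys, p_keys))
  cc <- fit$trace$edge_change_counts
  expect_equal(u, n_edges(prior) + cc[["added_beyond_prior"]])
  expect_equal(u, n_edges(fit$S) + cc[["removed_from_prior"]])
})

test_that("zero-penalty solve reduces to projected alternating descent", {
  sim <- tiny_instance(n_genes = 15, n_tfs = 2, n_samples = 10, n_edges = 30,
                       noise_sd = 0, seed = 6)
  ex <- sim$expr
  lap <- build_coexpression_laplacian(ex, knn_k = 3, tau = 0)
  p <- netrex_params(lambda = 0, kappa = 0, eta = 0, xi = 0, mu = 0,
                     a = 10, b = 100, max_iter = 5000, tol = 1e-13)
  fit <- palm_solve(ex, sim$S_true, lap, p)
  resid_palm <- sum((ex$values - as.matrix(sparsify(fit$S, ex$gene_ids,
                                                    fit$A$tf_ids)) %*%
                       fit$A$values)^2)
  # plain rank-M alternating least squares on the free problem
  M <- length(sim$S_true$tf_ids)
  S <- withr::with_seed(1, matrix(rnorm(nrow(ex$values) * M), ncol = M))
  for (i in 1:200) {
    A <- qr.solve(S, ex$values)
    S <- t(qr.solve(t(A), t(ex$values)))
  }
  resid_als <- sum((ex$values - S %*% A)^2)
  expect_lt(abs(resid_palm - resid_als), 1e-6 * max(1, sum(ex$values^2)))
})
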