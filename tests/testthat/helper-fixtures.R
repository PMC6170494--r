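# Small in-code fixtures shared across test files.

# A tiny deterministic expression matrix.
tiny_expr <- function(n_genes = 4, n_samples = 6, seed = 1) {
  vals <- withr::with_seed(seed, matrix(rnorm(n_genes * n_samples),
                                        n_genes, n_samples))
  expression_matrix(vals, sprintf("g%d", seq_len(n_genes)),
                    sprintf("s%d", seq_len(n_samples)))
}

# A small generative instance: E = S A (+ noise), prior = truth.
tiny_instance <- function(n_genes = 20, n_tfs = 3, n_samples = 12,
                          n_edges = 40, noise_sd = 0, seed = 1) {
  simulate_grn(simulation_config(n_genes = n_genes, n_tfs = n_tfs,
                                 n_samples = n_samples, n_true_edges = n_edges,
                                 noise_sd = noise_sd, tf_expression = FALSE,
                                 seed = seed))
}

# Naive term-by-term evaluation of the reprogramming objective, independent
# of the package's implementation (used as the oracle).
naive_objective <- function(E, S, A, S0, L, lambda, kappa, eta, xi, mu) {
  data_term <- 0.5 * sum((E - S %*% A)^2)
  removed <- sum(S0 != 0 & S == 0)
  added <- sum(S0 == 0 & S != 0)
  lap_term <- kappa * sum(diag(t(S) %*% as.matrix(L) %*% S))
  data_term + lambda * (removed + added) + lap_term +
    eta * sum(S != 0) + xi * sum(S^2) + mu * sum(A^2)
}

# The desk-scale benchmark consensus used by the protocol tests: three
# sample-count-scaled change penalties at the stronger sparsity level.
protocol_grid <- function(n_samples) {
  expand.grid(lambda = c(0.02, 0.05, 0.1) * n_samples, eta = 0.5,
              kappa = 0.1, xi = 0.1, mu = 0.1)
}

protocol_consensus <- function(expr, prior, seed, n_boot = 2) {
  infer_consensus(expr, prior, grid = protocol_grid(ncol(expr$values)),
                  n_boot = n_boot, seed = seed)
}

aupr_of <- function(ranked, sim) {
  evaluate_ranking(ranked, sim$S_true, gene_ids = sim$expr$gene_ids)$aupr
}
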