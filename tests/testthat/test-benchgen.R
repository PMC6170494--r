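test_that("simulation is exact without noise and reproducible with seed", {
  cfg <- simulation_config(n_genes = 30, n_tfs = 4, n_samples = 10,
                           n_true_edges = 60, noise_sd = 0, seed = 3)
  sim <- simulate_grn(cfg)
  S <- as.matrix(sparsify(sim$S_true, gene_ids = sim$expr$gene_ids))
  target_rows <- setdiff(sim$expr$gene_ids, sim$S_true$tf_ids)
  resid <- sim$expr$values - S %*% sim$A_true$values
  expect_equal(max(abs(resid[target_rows, ])), 0)

  sim2 <- simulate_grn(cfg)
  expect_identical(sim$expr$values, sim2$expr$values)
  expect_identical(sim$S_true$edges, sim2$S_true$edges)
})

test_that("every gene has a regulator and every TF a target", {
  sim <- simulate_grn(simulation_config(n_genes = 40, n_tfs = 10,
                                        n_samples = 5, n_true_edges = 55,
                                        seed = 5))
  S <- sparsify(sim$S_true)
  expect_true(all(Matrix::rowSums(S != 0) >= 1))
  expect_true(all(Matrix::colSums(S != 0) >= 1))
})

test_that("empirical noise level matches the configured sd", {
  cfg <- simulation_config(n_genes = 200, n_tfs = 10, n_samples = 60,
                           n_true_edges = 600, noise_sd = 0.3, seed = 7)
  sim <- simulate_grn(cfg)
  S <- as.matrix(sparsify(sim$S_true, gene_ids = sim$expr$gene_ids))
  resid <- sim$expr$values - S %*% sim$A_true$values
  targets <- setdiff(sim$expr$gene_ids, sim$S_true$tf_ids)
  expect_lt(abs(sd(resid[targets, ]) - 0.3) / 0.3, 0.05)
  # TF expression rows carry their own (wider) noise level
  expect_lt(abs(sd(resid[sim$S_true$tf_ids, ]) - cfg$tf_expr_noise_sd) /
              cfg$tf_expr_noise_sd, 0.05)
})

test_that("fixed-total corruption has exact true/false composition", {
  sim <- tiny_instance(n_genes = 25, n_tfs = 4, n_samples = 5, n_edges = 50,
                       seed = 11)
  truth <- paste(sim$S_true$edges$tf, sim$S_true$edges$gene)
  for (pct in c(0, 0.25, 0.6, 1)) {
    prior <- corrupt_prior_fixed_total(sim$S_true, pct, seed = 13)
    keys <- paste(prior$edges$tf, prior$edges$gene)
    expect_equal(n_edges(prior), n_edges(sim$S_true))
    expect_equal(sum(keys %in% truth), round(pct * n_edges(sim$S_true)))
  }
  p1 <- corrupt_prior_fixed_total(sim$S_true, 1, seed = 2)
  expect_setequal(paste(p1$edges$tf, p1$edges$gene), truth)
  p0 <- corrupt_prior_fixed_total(sim$S_true, 0, seed = 2)
  expect_length(intersect(paste(p0$edges$tf, p0$edges$gene), truth), 0)
})

test_that("fixed-true corruption supports the degenerate 0:1 ratio", {
  sim <- tiny_instance(n_genes = 25, n_tfs = 4, n_samples = 5, n_edges = 50,
                       seed = 12)
  truth <- paste(sim$S_true$edges$tf, sim$S_true$edges$gene)

  half <- corrupt_prior_fixed_true(sim$S_true, 0.5, 0, seed = 3)
  expect_equal(n_edges(half), 25L)
  expect_true(all(paste(half$edges$tf, half$edges$gene) %in% truth))

  # ratio 0:1 -> zero true edges, nominal count of false edges
  none <- corrupt_prior_fixed_true(sim$S_true, 0, 1, seed = 3)
  expect_equal(n_edges(none), 25L)
  expect_length(intersect(paste(none$edges$tf, none$edges$gene), truth), 0)

  mixed <- corrupt_prior_fixed_true(sim$S_true, 0.5, 2.0, seed = 3)
  keys <- paste(mixed$edges$tf, mixed$edges$gene)
  expect_equal(sum(keys %in% truth), 25L)
  expect_equal(sum(!(keys %in% truth)), 50L)
})

test_that("module deletion removes exactly the module's incoming edges", {
  sim <- tiny_instance(n_genes = 30, n_tfs = 4, n_samples = 5, n_edges = 60,
                       seed = 14)
  expect_equal(delete_module_edges(sim$S_true, character(0))$edges,
               sim$S_true$edges)
  expect_equal(n_edges(delete_module_edges(sim$S_true, sim$S_true$gene_ids)),
               0L)
  module <- sim$S_true$gene_ids[1:5]
  indeg <- sum(sim$S_true$edges$gene %in% module)
  pruned <- delete_module_edges(sim$S_true, module)
  expect_equal(n_edges(sim$S_true) - n_edges(pruned), indeg)
})

test_that("ranking evaluation hits the exact extremes", {
  sim <- tiny_instance(n_genes = 50, n_tfs = 4, n_samples = 5, n_edges = 100,
                       seed = 15)
  perfect <- rank_prior(sim$S_true)
  m <- evaluate_ranking(perfect, sim$S_true)
  expect_equal(m$aupr, 1)
  expect_equal(m$auroc, 1)

  # reversed ranking: gold edges at the very bottom of a 200-pair universe
  univ <- expand.grid(tf = sim$S_true$tf_ids, gene = sim$S_true$gene_ids,
                      stringsAsFactors = FALSE)
  gk <- paste(sim$S_true$edges$tf, sim$S_true$edges$gene)
  uk <- paste(univ$tf, univ$gene)
  reversed <- ranked_edge_list(univ$tf, univ$gene,
                               ifelse(uk %in% gk, 0, 1) + seq_along(uk) * 1e-9)
  m_rev <- evaluate_ranking(reversed, sim$S_true)
  expect_lte(m_rev$auroc, 0.01)
})

test_that("random rankings score near the gold density", {
  sim <- tiny_instance(n_genes = 60, n_tfs = 5, n_samples = 5, n_edges = 120,
                       seed = 16)
  univ <- expand.grid(tf = sim$S_true$tf_ids, gene = sim$S_true$gene_ids,
                      stringsAsFactors = FALSE)
  auprs <- vapply(1:20, function(s) {
    r <- ranked_edge_list(univ$tf, univ$gene,
                          withr::with_seed(s, runif(nrow(univ))))
    evaluate_ranking(r, sim$S_true)$aupr
  }, numeric(1))
  density <- 120 / nrow(univ)
  expect_lt(abs(mean(auprs) - density), 3 * sd(auprs) / sqrt(20))
})

test_that("auroc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  sim <- tiny_instance(n_genes = 20, n_tfs = 3, n_samples = 5, n_edges = 40,
                       seed = 17)
  univ <- expand.grid(tf = sim$S_true$tf_ids, gene = sim$S_true$gene_ids,
                      stringsAsFactors = FALSE)
  scores <- withr::with_seed(2, runif(nrow(univ)))
  r <- ranked_edge_list(univ$tf, univ$gene, scores)
  m <- evaluate_ranking(r, sim$S_true)
  labels <- paste(univ$tf, univ$gene) %in%
    paste(sim$S_true$edges$tf, sim$S_true$edges$gene)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(m$auroc, ref, tolerance = 1e-9)
})

test_that("novel-edge enrichment matches a log-space combinatorial oracle", {
  pool <- sprintf("e%04d", 1:1000)
  gold <- pool[1:30]
  pred <- c(pool[1:20], pool[101:180])  # 20 hits among 100 drawn
  got <- novel_edge_enrichment(pred, gold, pool)
  # oracle: exact tail from log-binomial coefficients
  logp_terms <- vapply(20:30, function(k) {
    lchoose(30, k) + lchoose(970, 100 - k) - lchoose(1000, 100)
  }, numeric(1))
  p_exact <- sum(exp(logp_terms))
  expect_equal(got, -log10(p_exact), tolerance = 1e-8)

  expect_identical(novel_edge_enrichment(pool[500:520], character(0), pool), 0)
  # fully saturated: P(X >= |gold|) with everything drawn = 1
  expect_identical(novel_edge_enrichment(pool, gold, pool) <= 1e-12, TRUE)
})
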