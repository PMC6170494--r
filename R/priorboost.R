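# PriorBoost: does the prior network actually help? Compares the
# data-consistency (fixed-support NCA residual) of a prior-based prediction
# against an expression-only tree-ensemble baseline across edge-count
# cutoffs. Positive scores mean the prior-based network explains the
# expression better than the prior-free one.

#' Expression-only tree-ensemble network inference
#'
#' A GENIE3-style baseline: for each target gene, a random-forest
#' regression predicts its expression across samples from the expression of
#' all TFs (excluding the target itself when it is a TF); the weight of
#' edge (tf, gene) is the ensemble importance (total impurity reduction) of
#' that TF. Target expression is standardized per gene so importances are
#' comparable across genes; all weights are pooled and ranked descending.
#'
#' @param expr an [expression_matrix()]; every TF must have a row.
#' @param tf_ids character vector of candidate regulator gene ids.
#' @param n_trees trees per forest.
#' @param seed integer seed (forests are seeded per target gene).
#' @return a [ranked_edge_list()] over all (tf, gene) pairs with tf != gene.
#' @export
baseline_infer <- function(expr, tf_ids, n_trees = 100L, seed = 1L) {
  tf_ids <- as.character(tf_ids)
  missing_tf <- setdiff(tf_ids, expr$gene_ids)
  if (length(missing_tf)) {
    stop("TF has no expression row: ", missing_tf[1])
  }
  E <- expr$values
  X_all <- t(E[tf_ids, , drop = FALSE])   # samples x TFs
  genes <- expr$gene_ids
  res_tf <- character(0); res_gene <- character(0); res_w <- numeric(0)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    preds <- setdiff(tf_ids, g)
    if (length(preds) == 0L) next
    y <- E[g, ]
    sdy <- stats::sd(y)
    if (sdy < 1e-12) {
      imp <- stats::setNames(rep(0, length(preds)), preds)
    } else {
      df <- data.frame(X_all[, preds, drop = FALSE], check.names = FALSE)
      df$.y <- (y - mean(y)) / sdy
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = n_trees,
        mtry = min(length(preds), ceiling(sqrt(length(tf_ids)))),
        importance = "impurity",
        seed = derive_seed(seed, gi),
        num.threads = 1L, verbose = FALSE)
      imp <- fit$variable.importance[preds]
      imp[is.na(imp)] <- 0
    }
    res_tf <- c(res_tf, preds)
    res_gene <- c(res_gene, rep(g, length(preds)))
    res_w <- c(res_w, as.numeric(imp))
  }
  ranked_edge_list(res_tf, res_gene, res_w)
}

#' PriorBoost score Q(G0)
#'
#' For each cutoff c, keeps the top c edges of the prior-based and baseline
#' ranked lists, computes the fixed-support NCA residual q of each support
#' ([nca_residual()]), and averages the differences:
#' `Q = mean_c [ q(baseline_c) - q(prior_based_c) ]`.
#' Positive Q: the prior-based network is more consistent with the
#' expression data, i.e. the prior is informative. Negative Q: the prior
#' may be misleading and an expression-only method is preferable.
#'
#' @param expr an [expression_matrix()].
#' @param prior_based a [ranked_edge_list()] from a prior-based method
#'   (any method; the score is method-agnostic).
#' @param baseline a [ranked_edge_list()] from an expression-only method.
#' @param cutoffs integer vector of edge-count cutoffs; `NULL` uses the
#'   deciles of the shorter list length.
#' @param nca_max_iter,nca_tol,seed passed to [nca_residual()].
#' @return list with `Q` and `per_cutoff` (data.frame of cutoff,
#'   q_baseline, q_prior_based).
#' @export
priorboost_score <- function(expr, prior_based, baseline, cutoffs = NULL,
                             nca_max_iter = 200L, nca_tol = 1e-8, seed = 1L) {
  K <- min(nrow(prior_based), nrow(baseline))
  if (is.null(cutoffs)) cutoffs <- unique(pmax(1L, round(seq(0.1, 1, 0.1) * K)))
  cutoffs <- as.integer(cutoffs)
  if (length(cutoffs) == 0L) stop("cutoff list is empty")
  if (any(cutoffs < 1L) || any(cutoffs > K)) {
    stop("cutoffs must lie in [1, min(list lengths)]")
  }
  tf_univ <- sort(unique(c(prior_based$tf, baseline$tf)))
  gene_univ <- expr$gene_ids
  qb <- qp <- numeric(length(cutoffs))
  for (ci in seq_along(cutoffs)) {
    c <- cutoffs[ci]
    supp_p <- as_edge_set(prior_based, top_k = c, tf_ids = tf_univ,
                          gene_ids = gene_univ)
    supp_b <- as_edge_set(baseline, top_k = c, tf_ids = tf_univ,
                          gene_ids = gene_univ)
    # one seed per cutoff, shared by both fits: q is then a deterministic
    # function of the support, so swapping the arguments exactly negates Q
    qp[ci] <- nca_residual(expr, supp_p, max_iter = nca_max_iter,
                           tol = nca_tol, seed = derive_seed(seed, ci))$q
    qb[ci] <- nca_residual(expr, supp_b, max_iter = nca_max_iter,
                           tol = nca_tol, seed = derive_seed(seed, ci))$q
  }
  list(Q = mean(qb - qp),
       per_cutoff = data.frame(cutoff = cutoffs, q_baseline = qb,
                               q_prior_based = qp))
}
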