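# Confidence scoring of inferred edges, bootstrap resampling, and
# rank-consensus aggregation.

#' Leave-one-TF-out edge confidence
#'
#' For every supported edge (i, j), compares the residual of gene i's linear
#' model with and without TF j's contribution:
#' `B(i,j) = 1 - ||E(i,) - sum_{k != j} S(i,k) A(k,)||^2 /
#'               ||E(i,) - S(i,) A||^2`.
#' Removing an informative TF inflates the numerator, so informative edges
#' have `B` far below 0; the importance used for ranking is `-B`
#' (equivalently `ratio - 1`). A zero full-model residual with a positive
#' leave-one-out residual yields importance `+Inf` (ranked first); a 0/0
#' ratio yields importance 0.
#'
#' @param expr an [expression_matrix()] (the one the solve used).
#' @param S a [grn_edge_set()] with solved weights, or a genes x TFs matrix.
#' @param A an [activity_matrix()].
#' @return data.frame of class `confidence_matrix` with columns
#'   `tf`, `gene`, `B`, `importance` (one row per supported edge).
#' @export
edge_confidence <- function(expr, S, A) {
  Amat <- A$values
  if (inherits(S, "grn_edge_set")) {
    Smat <- as.matrix(sparsify(S, gene_ids = expr$gene_ids, tf_ids = A$tf_ids))
    edges <- S$edges
  } else {
    Smat <- as.matrix(S)
    nz <- which(Smat != 0, arr.ind = TRUE)
    edges <- data.frame(tf = A$tf_ids[nz[, 2]],
                        gene = expr$gene_ids[nz[, 1]],
                        weight = Smat[nz])
  }
  if (nrow(edges) == 0L) stop("no supported edges to score")
  E <- expr$values
  R <- E - Smat %*% Amat                       # full-model residual rows
  denom_row <- rowSums(R^2)
  gi <- match(edges$gene, expr$gene_ids)
  tj <- match(edges$tf, A$tf_ids)
  if (anyNA(gi) || anyNA(tj)) stop("edge outside the expression/TF universe")
  numer <- vapply(seq_len(nrow(edges)), function(r) {
    sum((R[gi[r], ] + Smat[gi[r], tj[r]] * Amat[tj[r], ])^2)
  }, numeric(1))
  denom <- denom_row[gi]
  ratio <- ifelse(denom > 0, numer / denom,
                  ifelse(numer > 0, Inf, 1))
  out <- data.frame(tf = edges$tf, gene = edges$gene,
                    B = 1 - ratio, importance = ratio - 1)
  class(out) <- c("confidence_matrix", "data.frame")
  out
}

#' Rank the edges of a solved network by importance
#'
#' @inheritParams edge_confidence
#' @return a [ranked_edge_list()] whose weights are the importances.
#' @export
rank_edges <- function(expr, S, A) {
  conf <- edge_confidence(expr, S, A)
  w <- conf$importance
  # +Inf sentinels must sort first but remain finite in the output weights
  if (any(is.infinite(w))) {
    top <- max(w[is.finite(w)], 0)
    w[is.infinite(w)] <- top + 1
  }
  ranked_edge_list(conf$tf, conf$gene, w)
}

#' Consensus over ranked edge lists
#'
#' Borda/average-rank aggregation: each edge's score is its mean rank over
#' the lists, where an edge absent from a list is charged rank
#' `(length of that list) + 1`. The consensus is sorted by ascending mean
#' rank with `(tf, gene)` lexicographic tie-break.
#'
#' @param lists a non-empty list of [ranked_edge_list()] objects.
#' @return a [ranked_edge_list()]; weights are `-mean_rank` so that rank 1
#'   corresponds to the smallest mean rank.
#' @export
aggregate_rankings <- function(lists) {
  if (length(lists) == 0L) stop("need at least one ranked list")
  keys <- unique(unlist(lapply(lists, function(l) {
    paste(l$tf, l$gene, sep = "\r")
  })))
  total <- numeric(length(keys))
  for (l in lists) {
    lk <- paste(l$tf, l$gene, sep = "\r")
    pos <- match(keys, lk)
    r <- ifelse(is.na(pos), nrow(l) + 1L, l$rank[pos])
    total <- total + r
  }
  mean_rank <- total / length(lists)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ranked_edge_list(vapply(parts, `[[`, "", 1L),
                   vapply(parts, `[[`, "", 2L),
                   -mean_rank)
}

#' Bootstrap-aggregated edge ranking
#'
#' Resamples the expression sample columns with replacement (replicate
#' `r` uses seed `seed + r`), rebuilds the coexpression Laplacian on each
#' resampled matrix, re-solves the reprogramming problem, ranks edges by
#' importance, and aggregates the replicate rankings with
#' [aggregate_rankings()]. Replicates whose solve fails are dropped with a
#' warning; the run aborts if at least half fail.
#'
#' @param expr an [expression_matrix()] (preprocessed).
#' @param prior the prior [grn_edge_set()].
#' @param params a [netrex_params()].
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer master seed.
#' @param lap_knn_k,lap_tau coexpression graph parameters
#'   (see [build_coexpression_laplacian()]).
#' @return a consensus [ranked_edge_list()].
#' @export
bootstrap_rank <- function(expr, prior, params = netrex_params(),
                           n_boot = 10L, seed = 1L,
                           lap_knn_k = 10L, lap_tau = 0.5) {
  stopifnot(n_boot >= 1)
  lists <- vector("list", n_boot)
  for (r in seq_len(n_boot)) {
    cols <- with_seed(seed + r,
                      sample.int(ncol(expr$values), replace = TRUE))
    eb <- expression_matrix(expr$values[, cols, drop = FALSE],
                            expr$gene_ids,
                            paste0("b", seq_along(cols)))
    lists[[r]] <- tryCatch({
      lap <- build_coexpression_laplacian(eb, knn_k = lap_knn_k, tau = lap_tau)
      fit <- palm_solve(eb, prior, lap, params)
      rank_edges(eb, fit$S, fit$A)
    }, error = function(e) {
      warning(sprintf("bootstrap replicate %d dropped: %s", r,
                      conditionMessage(e)))
      NULL
    })
  }
  ok <- !vapply(lists, is.null, logical(1))
  if (sum(ok) < n_boot / 2) stop("more than half of bootstrap replicates failed")
  aggregate_rankings(lists[ok])
}

#' Consensus inference over a parameter grid
#'
#' Runs the full solve-and-rank pipeline once per parameter setting (each
#' setting optionally bootstrap-aggregated) and combines the per-setting
#' rankings into one consensus list. This is the recommended way to obtain
#' a final network when no ground truth is available for tuning.
#'
#' @param expr an [expression_matrix()] (raw; preprocessing applied here).
#' @param prior the prior [grn_edge_set()].
#' @param grid data.frame with columns among `lambda`, `kappa`, `eta`,
#'   `xi`, `mu`; missing columns take [netrex_params()] defaults. `NULL`
#'   uses [default_param_grid()] scaled to the sample count.
#' @param n_boot bootstrap replicates per setting (1 = single solve).
#' @param seed master seed.
#' @param preprocess expression preprocessing method.
#' @param lap_knn_k,lap_tau coexpression graph parameters.
#' @param max_iter,tol solver controls applied to every grid setting.
#' @return a consensus [ranked_edge_list()].
#' @export
infer_consensus <- function(expr, prior, grid = NULL, n_boot = 1L, seed = 1L,
                            preprocess = "z-score-genes",
                            lap_knn_k = 10L, lap_tau = 0.5,
                            max_iter = 500L, tol = 1e-6) {
  if (is.null(grid)) grid <- default_param_grid(ncol(expr$values))
  ex <- preprocess_expression(expr, preprocess)
  lap <- build_coexpression_laplacian(ex, knn_k = lap_knn_k, tau = lap_tau)
  lists <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- netrex_params(
      lambda = grid$lambda[g] %||% 5,
      kappa = grid$kappa[g] %||% 0.1,
      eta = grid$eta[g] %||% 0.5,
      xi = grid$xi[g] %||% 0.1,
      mu = grid$mu[g] %||% 0.1,
      max_iter = max_iter, tol = tol,
      seed = derive_seed(seed, g))
    lists[[g]] <- if (n_boot > 1L) {
      bootstrap_rank(ex, prior, p, n_boot = n_boot,
                     seed = derive_seed(seed, 1000L + g),
                     lap_knn_k = lap_knn_k, lap_tau = lap_tau)
    } else {
      fit <- palm_solve(ex, prior, lap, p)
      rank_edges(ex, fit$S, fit$A)
    }
  }
  aggregate_rankings(lists)
}

#' Default parameter grid for consensus inference
#'
#' The edge-change penalty `lambda` is scaled by the sample count: the
#' data-fit term of the objective grows linearly with the number of
#' samples while the per-edge penalties do not, so a sample-size-invariant
#' addition/removal threshold requires `lambda` proportional to `L`. The
#' grid crosses three change-penalty levels with two sparsity levels.
#'
#' @param n_samples number of expression samples the solve will see.
#' @return data.frame of penalty settings crossed over lambda and eta.
#' @export
default_param_grid <- function(n_samples = 100L) {
  expand.grid(lambda = c(0.02, 0.05, 0.1) * n_samples, eta = c(0.1, 0.5),
              kappa = 0.1, xi = 0.1, mu = 0.1)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x
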