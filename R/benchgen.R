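# Synthetic ground truth, controlled prior corruption, and ranked-edge
# evaluation. The generative model is the same linear activity model the
# solver assumes: E = S_true A_true + noise, with a sparse uniformly drawn
# support in which every gene has a regulator and every TF a target.

#' Simulation configuration
#'
#' @param n_genes,n_tfs,n_samples dimensions (N, M, L).
#' @param n_true_edges size of the ground-truth support; must be at least
#'   `max(n_genes, n_tfs)` so the coverage constraints are satisfiable.
#' @param noise_sd standard deviation of the iid Gaussian expression noise.
#' @param weight_range magnitude range of the regulatory potentials
#'   (uniform, random sign).
#' @param activity_sd standard deviation of the iid Gaussian TF activities.
#' @param tf_expression if `TRUE` (default), the expression matrix also
#'   carries one row per TF gene, generated as that TF's activity plus
#'   noise (`E(tf,:) = A(tf,:) + noise`), and the corresponding unit-weight
#'   self-edge joins the ground truth. This emulates real data, where TFs
#'   are themselves profiled genes whose mRNA only partially tracks their
#'   activity, and is required by expression-only baselines that regress
#'   targets on TF expression.
#' @param tf_expr_noise_sd noise standard deviation of the TF expression
#'   rows. The default, `sqrt(3) * activity_sd`, makes TF mRNA correlate
#'   with TF activity at about 0.5 — the weak coupling between transcript
#'   level and regulatory activity that motivates activity-based models.
#' @param seed master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 300L, n_tfs = 30L, n_samples = 100L,
                              n_true_edges = 1500L, noise_sd = 0.3,
                              weight_range = c(0.5, 1.5), activity_sd = 1,
                              tf_expression = TRUE,
                              tf_expr_noise_sd = sqrt(3) * activity_sd,
                              seed = 1L) {
  stopifnot(n_genes >= 2, n_tfs >= 1, n_samples >= 2, noise_sd >= 0,
            n_true_edges <= n_genes * n_tfs,
            length(weight_range) == 2, weight_range[1] <= weight_range[2])
  if (n_true_edges < max(n_genes, n_tfs)) {
    stop("n_true_edges too small to give every gene a regulator ",
         "and every TF a target")
  }
  if (n_tfs > n_genes) stop("need n_genes >= n_tfs to cover every TF")
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_samples = as.integer(n_samples),
                 n_true_edges = as.integer(n_true_edges),
                 noise_sd = noise_sd, weight_range = weight_range,
                 activity_sd = activity_sd,
                 tf_expression = isTRUE(tf_expression),
                 tf_expr_noise_sd = tf_expr_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a ground-truth GRN and expression data
#'
#' Draws a sparse support uniformly (subject to every gene having at least
#' one regulator and every TF at least one target), regulatory-potential
#' weights of uniform magnitude and random sign, iid Gaussian activities,
#' and `E = S_true A_true + noise`. Fully determined by `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list with `S_true` (a [grn_edge_set()]), `A_true`
#'   (an [activity_matrix()]), and `expr` (an [expression_matrix()]).
#' @export
simulate_grn <- function(cfg = simulation_config()) {
  N <- cfg$n_genes; M <- cfg$n_tfs; L <- cfg$n_samples
  gene_ids <- sprintf("g%03d", seq_len(N))
  tf_ids <- sprintf("tf%02d", seq_len(M))
  with_seed(cfg$seed, {
    # one uniform regulator per gene, then repair TF coverage by moving a
    # regulator from a multiply-covered gene slot to each uncovered TF
    reg <- sample.int(M, N, replace = TRUE)
    for (t in which(tabulate(reg, M) == 0L)) {
      movable <- which(tabulate(reg, M)[reg] >= 2L)
      reg[movable[sample.int(length(movable), 1L)]] <- t
    }
    idx <- (reg - 1L) * N + seq_len(N)         # column-major (gene, tf) index
    extra_n <- cfg$n_true_edges - N
    pool <- setdiff(seq_len(N * M), idx)
    if (extra_n > 0L) idx <- c(idx, sample(pool, extra_n))
    w <- stats::runif(length(idx), cfg$weight_range[1], cfg$weight_range[2]) *
      sample(c(-1, 1), length(idx), replace = TRUE)
    A <- matrix(stats::rnorm(M * L, sd = cfg$activity_sd), M, L)
    noise <- matrix(stats::rnorm(N * L, sd = cfg$noise_sd), N, L)
    S <- matrix(0, N, M)
    S[idx] <- w
    E <- S %*% A + noise
    if (cfg$tf_expression) {
      # TF genes: expression = own activity + noise, self-edge in the truth
      E <- rbind(E, A + matrix(stats::rnorm(M * L, sd = cfg$tf_expr_noise_sd),
                               M, L))
      S <- rbind(S, diag(1, M))
      gene_ids <- c(gene_ids, tf_ids)
    }
    rownames(E) <- gene_ids
    colnames(E) <- sprintf("s%03d", seq_len(L))
    list(S_true = densify(S, gene_ids = gene_ids, tf_ids = tf_ids),
         A_true = activity_matrix(A, tf_ids, colnames(E)),
         expr = expression_matrix(E, gene_ids, colnames(E)))
  })
}

edge_keys <- function(net) paste(net$edges$tf, net$edges$gene, sep = "\r")

all_pair_keys <- function(tf_ids, gene_ids) {
  paste(rep(tf_ids, each = length(gene_ids)),
        rep(gene_ids, times = length(tf_ids)), sep = "\r")
}

keys_to_edge_set <- function(keys, weights, tf_ids, gene_ids) {
  parts <- strsplit(keys, "\r", fixed = TRUE)
  grn_edge_set(data.frame(tf = vapply(parts, `[[`, "", 1L),
                          gene = vapply(parts, `[[`, "", 2L),
                          weight = weights),
               tf_ids = tf_ids, gene_ids = gene_ids)
}

#' Corrupt a prior at fixed total edge count
#'
#' Builds a noisy prior with exactly `|S_true|` edges:
#' `round(pct_true * |S_true|)` drawn uniformly from the true edges and the
#' remainder uniformly from the non-edges.
#'
#' @param S_true the ground-truth [grn_edge_set()].
#' @param pct_true fraction of true edges in `[0, 1]`.
#' @param seed integer seed.
#' @return a [grn_edge_set()] over the same universe, all weights 1.
#' @export
corrupt_prior_fixed_total <- function(S_true, pct_true, seed = 1L) {
  stopifnot(pct_true >= 0, pct_true <= 1)
  true_keys <- edge_keys(S_true)
  K <- length(true_keys)
  n_true <- round(pct_true * K)
  n_false <- K - n_true
  non_edges <- setdiff(all_pair_keys(S_true$tf_ids, S_true$gene_ids), true_keys)
  if (n_false > length(non_edges)) stop("not enough non-edges for the false part")
  with_seed(seed, {
    keep <- if (n_true > 0) sample(true_keys, n_true) else character(0)
    fake <- if (n_false > 0) sample(non_edges, n_false) else character(0)
    keys_to_edge_set(c(keep, fake), 1, S_true$tf_ids, S_true$gene_ids)
  })
}

#' Corrupt a prior at fixed true edge count
#'
#' Builds a noisy prior with `n_t = round(true_fraction_of_gold * |S_true|)`
#' true edges plus `round(false_per_true * n_t_nominal)` false edges, where
#' the nominal true count `n_t_nominal` is taken from
#' `nominal_fraction_of_gold` even when the true part is zeroed — so the
#' degenerate "0:1 true-to-false ratio" case yields a purely false prior of
#' the nominal size.
#'
#' @param S_true the ground-truth [grn_edge_set()].
#' @param true_fraction_of_gold fraction of gold edges kept as true.
#' @param false_per_true false edges per nominal true edge.
#' @param seed integer seed.
#' @param nominal_fraction_of_gold base fraction for sizing the false part
#'   (default 0.5: half the gold edges).
#' @return a [grn_edge_set()], all weights 1.
#' @export
corrupt_prior_fixed_true <- function(S_true, true_fraction_of_gold,
                                     false_per_true, seed = 1L,
                                     nominal_fraction_of_gold = 0.5) {
  stopifnot(true_fraction_of_gold >= 0, true_fraction_of_gold <= 1,
            false_per_true >= 0)
  true_keys <- edge_keys(S_true)
  K <- length(true_keys)
  n_t <- round(true_fraction_of_gold * K)
  n_t_nominal <- round(nominal_fraction_of_gold * K)
  n_f <- round(false_per_true * n_t_nominal)
  non_edges <- setdiff(all_pair_keys(S_true$tf_ids, S_true$gene_ids), true_keys)
  if (n_f > length(non_edges)) stop("not enough non-edges for the false part")
  if (n_t + n_f == 0L) stop("requested an empty prior")
  with_seed(seed, {
    keep <- if (n_t > 0) sample(true_keys, n_t) else character(0)
    fake <- if (n_f > 0) sample(non_edges, n_f) else character(0)
    keys_to_edge_set(c(keep, fake), 1, S_true$tf_ids, S_true$gene_ids)
  })
}

#' Delete all edges into a gene module
#'
#' Models a truly differential module: the prior agrees with the truth
#' everywhere except that every edge targeting a module gene is removed.
#'
#' @param S_true a [grn_edge_set()].
#' @param module_genes character vector of module gene ids (subset of the
#'   gene universe).
#' @return a [grn_edge_set()] without the module's incoming edges.
#' @export
delete_module_edges <- function(S_true, module_genes) {
  if (!all(module_genes %in% S_true$gene_ids)) {
    stop("module gene outside the gene universe: ",
         setdiff(module_genes, S_true$gene_ids)[1])
  }
  e <- S_true$edges
  e <- e[!(e$gene %in% module_genes), , drop = FALSE]
  grn_edge_set(e, tf_ids = S_true$tf_ids, gene_ids = S_true$gene_ids)
}

#' AUPR and AUROC of a ranked edge list against a gold standard
#'
#' Scores every candidate edge in the universe (all TF x gene pairs by
#' default, DREAM style): ranked edges in rank order, unranked edges below
#' all ranked ones in deterministic `(tf, gene)` lexicographic order. AUPR
#' is step-wise precision-recall integration (average precision); AUROC is
#' the Mann-Whitney statistic of gold vs non-gold positions.
#'
#' @param ranked a [ranked_edge_list()].
#' @param gold the true [grn_edge_set()].
#' @param tf_ids,gene_ids the candidate universe (defaults: the gold's).
#' @return list with `aupr` and `auroc`.
#' @export
evaluate_ranking <- function(ranked, gold, tf_ids = gold$tf_ids,
                             gene_ids = gold$gene_ids) {
  if (n_edges(gold) == 0L) stop("gold standard is empty")
  univ <- all_pair_keys(tf_ids, gene_ids)
  rk <- paste(ranked$tf, ranked$gene, sep = "\r")
  if (!all(rk %in% univ)) stop("ranked edge outside the candidate universe")
  unranked <- sort(setdiff(univ, rk))
  order_keys <- c(rk[order(ranked$rank)], unranked)
  gold_keys <- edge_keys(gold)
  if (!all(gold_keys %in% univ)) stop("gold edge outside the candidate universe")
  is_gold <- order_keys %in% gold_keys
  n_pos <- sum(is_gold)
  n_all <- length(order_keys)
  n_neg <- n_all - n_pos
  tp <- cumsum(is_gold)
  precision_at_hit <- (tp / seq_len(n_all))[is_gold]
  aupr <- sum(precision_at_hit) / n_pos
  pos_ranks <- which(is_gold)
  auroc <- (sum(n_all + 1 - pos_ranks) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  list(aupr = aupr, auroc = auroc)
}

#' Rank a prior as-is for baseline comparison
#'
#' Turns an unweighted edge set into a ranked list (all weights equal, so
#' the order is the deterministic lexicographic tie-break); used to measure
#' the AUPR of the prior itself.
#'
#' @param net a [grn_edge_set()].
#' @return a [ranked_edge_list()].
#' @export
rank_prior <- function(net) {
  ranked_edge_list(net$edges$tf, net$edges$gene, net$edges$weight)
}

#' Enrichment of newly predicted edges in novel gold interactions
#'
#' Hypergeometric upper-tail enrichment of `predicted_new` hits in
#' `novel_gold`, drawn from the pool of all new candidate edges:
#' draws `|predicted_new|`, marked `|novel_gold ∩ pool_new|`, universe
#' `|pool_new|`; returned as `-log10(p)`.
#'
#' @param predicted_new character keys or [grn_edge_set()] of the
#'   method's newly predicted edges (subset of `pool_new`).
#' @param novel_gold the novel true interactions.
#' @param pool_new the candidate pool of new edges.
#' @return `-log10(p)` via [hypergeom_enrichment()].
#' @export
novel_edge_enrichment <- function(predicted_new, novel_gold, pool_new) {
  as_keys <- function(x) {
    if (inherits(x, "grn_edge_set")) edge_keys(x) else as.character(x)
  }
  pred <- unique(as_keys(predicted_new))
  gold <- unique(as_keys(novel_gold))
  pool <- unique(as_keys(pool_new))
  if (!all(pred %in% pool)) stop("predicted_new must be a subset of pool_new")
  marked <- intersect(gold, pool)
  hits <- length(intersect(pred, marked))
  hypergeom_enrichment(hits, length(pred), length(marked), length(pool))
}
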