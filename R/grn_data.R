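# Domain types and readers/writers: expression matrices, weighted edge sets,
# TF activity matrices, ranked edge lists, and solver parameter bundles.

#' Construct an expression matrix
#'
#' Wraps a numeric genes-by-samples matrix with identifier bookkeeping.
#' Orientation is fixed: genes in rows, samples in columns.
#'
#' @param values numeric matrix, N genes x L samples.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param sample_ids character vector of unique sample identifiers (columns).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1])
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("need at least 2 genes and 2 samples")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d samples>\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path path to a tab-separated file.
#' @param impute `"none"` (reject missing values, the default) or
#'   `"row-mean"` (replace missing cells by the gene's row mean).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, impute = c("none", "row-mean")) {
  impute <- match.arg(impute)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  gene_ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))[1]
      stop(sprintf("non-numeric cell at gene row %s, sample column %s",
                   gene_ids[bad], names(body)[j]))
    }
  }
  values <- as.matrix(body)
  if (anyNA(values)) {
    if (impute == "none") {
      idx <- which(is.na(values), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at gene %s, sample %s (use impute = 'row-mean')",
                   gene_ids[idx[1]], colnames(values)[idx[2]]))
    }
    for (i in seq_len(nrow(values))) {
      miss <- is.na(values[i, ])
      if (any(miss)) values[i, miss] <- mean(values[i, !miss])
    }
  }
  expression_matrix(values, gene_ids, colnames(values))
}

#' Write an expression matrix to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::data.table(gene = expr$gene_ids)
  vals <- as.data.frame(signif(expr$values, 12))
  names(vals) <- expr$sample_ids
  data.table::fwrite(cbind(dt, vals), path, sep = "\t")
  invisible(path)
}

#' Construct a weighted TF-to-gene edge set
#'
#' A directed bipartite regulatory network: TFs regulate target genes.
#' A TF may itself appear among the target genes (self-regulation allowed).
#'
#' @param edges data.frame with columns `tf`, `gene` and optionally `weight`
#'   (default 1.0).
#' @param tf_ids,gene_ids optional explicit id universes; defaults are the
#'   sorted distinct endpoints found in `edges`.
#' @return an object of class `grn_edge_set`.
#' @export
grn_edge_set <- function(edges, tf_ids = NULL, gene_ids = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0 && !all(c("tf", "gene") %in% names(edges))) {
    stop("edges must have columns tf, gene")
  }
  if (nrow(edges) == 0) {
    edges <- data.frame(tf = character(), gene = character(), weight = double())
  }
  edges$tf <- as.character(edges$tf)
  edges$gene <- as.character(edges$gene)
  if (is.null(edges$weight)) edges$weight <- rep(1.0, nrow(edges))
  edges$weight <- as.double(edges$weight)
  key <- paste(edges$tf, edges$gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    parts <- strsplit(dup, "\r", fixed = TRUE)[[1]]
    w <- edges$weight[key == dup]
    if (length(unique(w)) > 1L) {
      stop(sprintf("duplicate edge (%s, %s) with conflicting weights",
                   parts[1], parts[2]))
    }
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    key <- key[keep]
  }
  if (is.null(tf_ids)) tf_ids <- sort(unique(edges$tf))
  if (is.null(gene_ids)) gene_ids <- sort(unique(edges$gene))
  tf_ids <- as.character(tf_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(tf_ids)) stop("duplicate tf id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene id")
  if (!all(edges$tf %in% tf_ids)) {
    stop("edge TF not in tf_ids: ", setdiff(edges$tf, tf_ids)[1])
  }
  if (!all(edges$gene %in% gene_ids)) {
    stop("edge gene not in gene_ids: ", setdiff(edges$gene, gene_ids)[1])
  }
  rownames(edges) <- NULL
  structure(list(edges = edges[c("tf", "gene", "weight")],
                 tf_ids = tf_ids, gene_ids = gene_ids),
            class = "grn_edge_set")
}

#' @export
print.grn_edge_set <- function(x, ...) {
  cat(sprintf("<grn_edge_set: %d edges, %d TFs, %d genes>\n",
              nrow(x$edges), length(x$tf_ids), length(x$gene_ids)))
  invisible(x)
}

#' Number of edges in an edge set
#' @param net a [grn_edge_set()].
#' @return integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

# Read a TSV whose header row is optional. A first row is treated as a
# header when it matches the expected column names, or (for >= 3 columns)
# when its third field is non-numeric. Headerless 2-column files of pure
# identifiers are common for edge and pair lists.
read_tsv_optional_header <- function(path, expected_names) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) > 0) {
    first <- as.character(dt[1, ])
    looks_named <- all(tolower(first[seq_along(expected_names)]) ==
                         expected_names[seq_len(min(length(first),
                                                    length(expected_names)))])
    third_nonnum <- ncol(dt) >= 3 &&
      is.na(suppressWarnings(as.numeric(first[3])))
    if (looks_named || third_nonnum) dt <- dt[-1, , drop = FALSE]
  }
  dt
}

#' Read a TF-to-gene edge list from TSV
#'
#' Columns: `tf`, `gene`, optional `weight` (assumed 1.0 when absent).
#' A header row is optional and auto-detected.
#'
#' @param path path to the TSV file.
#' @param tf_ids,gene_ids optional explicit id universes.
#' @return a [grn_edge_set()].
#' @export
read_edge_list <- function(path, tf_ids = NULL, gene_ids = NULL) {
  dt <- read_tsv_optional_header(path, c("tf", "gene"))
  if (ncol(dt) < 2L) stop("edge list needs at least 2 columns (tf, gene)")
  edges <- data.frame(tf = as.character(dt[[1]]), gene = as.character(dt[[2]]))
  if (ncol(dt) >= 3L) edges$weight <- as.double(dt[[3]])
  grn_edge_set(edges, tf_ids = tf_ids, gene_ids = gene_ids)
}

#' Write an edge set (or ranked edge list) to TSV
#'
#' @param net a [grn_edge_set()] or [ranked_edge_list()].
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  df <- if (inherits(net, "grn_edge_set")) net$edges else as.data.frame(net)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Restrict a prior network to expressed genes
#'
#' Drops every edge whose TF or target gene has no expression row; the id
#' universes are intersected with the expression gene set.
#'
#' @param prior a [grn_edge_set()].
#' @param expr an [expression_matrix()].
#' @return a [grn_edge_set()] over the intersected universe.
#' @export
restrict_to_expressed <- function(prior, expr) {
  keep_tf <- intersect(prior$tf_ids, expr$gene_ids)
  keep_gene <- intersect(prior$gene_ids, expr$gene_ids)
  e <- prior$edges
  e <- e[e$tf %in% keep_tf & e$gene %in% keep_gene, , drop = FALSE]
  if (nrow(e) == 0) {
    warning("no prior edges remain after restricting to expressed genes")
  }
  grn_edge_set(e, tf_ids = keep_tf, gene_ids = keep_gene)
}

#' Materialize an edge set as a sparse adjacency matrix
#'
#' Rows are genes, columns TFs, entries the regulatory-potential weights.
#'
#' @param net a [grn_edge_set()].
#' @param gene_ids,tf_ids row/column universes (default: the edge set's own).
#' @return a `dgCMatrix` of dimension genes x TFs.
#' @export
sparsify <- function(net, gene_ids = net$gene_ids, tf_ids = net$tf_ids) {
  i <- match(net$edges$gene, gene_ids)
  j <- match(net$edges$tf, tf_ids)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint outside requested universe")
  Matrix::sparseMatrix(i = i, j = j, x = net$edges$weight,
                       dims = c(length(gene_ids), length(tf_ids)),
                       dimnames = list(gene_ids, tf_ids))
}

#' Convert an adjacency matrix back to an edge set
#'
#' Inverse of [sparsify()]: every structural non-zero becomes an edge.
#'
#' @param S genes x TFs matrix with dimnames; zero entries are dropped.
#' @param tf_ids,gene_ids id universes (default: the dimnames).
#' @return a [grn_edge_set()].
#' @export
densify <- function(S, gene_ids = rownames(S), tf_ids = colnames(S)) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  S <- Matrix::drop0(S)
  tri <- Matrix::summary(S)
  grn_edge_set(data.frame(tf = tf_ids[tri$j], gene = gene_ids[tri$i],
                          weight = tri$x),
               tf_ids = tf_ids, gene_ids = gene_ids)
}

#' Construct a TF activity matrix
#'
#' Latent per-sample regulatory activities, one row per TF. Activities are
#' box-bounded: the solver keeps every entry within `[-b, b]`.
#'
#' @param values numeric matrix, M TFs x L samples.
#' @param tf_ids character row identifiers.
#' @param sample_ids optional character column identifiers.
#' @return an object of class `activity_matrix`.
#' @export
activity_matrix <- function(values, tf_ids = rownames(values),
                            sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  tf_ids <- as.character(tf_ids)
  if (nrow(values) != length(tf_ids)) stop("tf_ids length mismatch")
  if (anyDuplicated(tf_ids)) stop("duplicate tf id")
  rownames(values) <- tf_ids
  if (!is.null(sample_ids)) colnames(values) <- as.character(sample_ids)
  structure(list(values = values, tf_ids = tf_ids), class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix: %d TFs x %d samples>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a ranked edge list
#'
#' The exchange format between inference, aggregation and evaluation:
#' TF-to-gene edges with confidence weights and dense integer ranks
#' (rank 1 = highest weight). Ties in weight are broken by `(tf, gene)`
#' lexicographic order so ranking is deterministic.
#'
#' @param tf,gene character vectors.
#' @param weight numeric confidence weights.
#' @return a data.frame of class `ranked_edge_list` with columns
#'   `tf`, `gene`, `weight`, `rank`, sorted by rank.
#' @export
ranked_edge_list <- function(tf, gene, weight) {
  tf <- as.character(tf); gene <- as.character(gene)
  weight <- as.double(weight)
  stopifnot(length(tf) == length(gene), length(tf) == length(weight))
  if (anyDuplicated(paste(tf, gene, sep = "\r"))) {
    stop("duplicate (tf, gene) pair in ranked list")
  }
  ord <- order(-weight, tf, gene, method = "radix")
  out <- data.frame(tf = tf[ord], gene = gene[ord], weight = weight[ord],
                    rank = seq_along(ord))
  class(out) <- c("ranked_edge_list", "data.frame")
  out
}

#' Read a ranked edge list from TSV
#'
#' @param path TSV with columns tf, gene, weight (rank recomputed on load).
#' @return a [ranked_edge_list()].
#' @export
read_ranked_edge_list <- function(path) {
  dt <- read_tsv_optional_header(path, c("tf", "gene", "weight"))
  if (ncol(dt) < 3L) stop("ranked list needs columns tf, gene, weight")
  ranked_edge_list(dt[[1]], dt[[2]], as.double(dt[[3]]))
}

#' Convert a ranked edge list to an edge set
#'
#' @param ranked a [ranked_edge_list()].
#' @param top_k optional truncation to the top `top_k` ranks.
#' @param tf_ids,gene_ids optional explicit universes.
#' @return a [grn_edge_set()] whose weights are the confidence weights.
#' @export
as_edge_set <- function(ranked, top_k = NULL, tf_ids = NULL, gene_ids = NULL) {
  df <- as.data.frame(ranked)
  if (!is.null(top_k)) df <- df[df$rank <= top_k, , drop = FALSE]
  grn_edge_set(df[c("tf", "gene", "weight")], tf_ids = tf_ids,
               gene_ids = gene_ids)
}

#' Solver parameter bundle
#'
#' Penalty weights of the reprogramming objective and solver controls.
#' `lambda` prices each edge change away from the prior; `kappa` weights the
#' coexpression graph-embedding term; `eta` and `xi` form the l0 elastic net
#' (sparsity with a grouping effect); `mu` keeps activities smooth.
#' `a` and `b` are the box bounds on regulatory potentials and activities.
#'
#' The data-fit term grows linearly with the number of samples while the
#' per-edge penalties do not, so `lambda` (and to a lesser degree `eta`)
#' should scale with the sample count; the defaults are calibrated for
#' data with on the order of 100 samples (`lambda ~ 0.05 * n_samples`).
#' See [default_param_grid()] for the scaled consensus grid.
#'
#' @param lambda,kappa,eta,xi,mu non-negative penalty weights.
#' @param a,b positive box bounds; `b = NULL` defaults to `max(abs(E))`
#'   at solve time so activities live on the expression scale.
#' @param max_iter,tol PALM iteration cap and relative objective tolerance.
#' @param seed integer seed for any downstream stochastic step.
#' @return an object of class `netrex_params`.
#' @export
netrex_params <- function(lambda = 5, kappa = 0.1, eta = 0.5, xi = 0.1,
                          mu = 0.1, a = 1, b = NULL, max_iter = 500L,
                          tol = 1e-6, seed = 1L) {
  stopifnot(lambda >= 0, kappa >= 0, eta >= 0, xi >= 0, mu >= 0, a > 0,
            is.null(b) || b > 0, max_iter >= 1, tol > 0)
  structure(list(lambda = lambda, kappa = kappa, eta = eta, xi = xi, mu = mu,
                 a = a, b = b, max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "netrex_params")
}

# z-score every gene row (constant rows are centered only); the default
# preprocessing before solving -- the linear model with box-bounded
# activities is scale sensitive.
zscore_genes <- function(expr) {
  v <- expr$values
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  sd[sd < 1e-12] <- 1
  expression_matrix((v - mu) / sd, expr$gene_ids, expr$sample_ids)
}

#' Preprocess an expression matrix
#'
#' @param expr an [expression_matrix()].
#' @param method `"z-score-genes"` (default), `"center-genes"`, or `"none"`.
#' @return a preprocessed [expression_matrix()].
#' @export
preprocess_expression <- function(expr,
                                  method = c("z-score-genes", "center-genes",
                                             "none")) {
  method <- match.arg(method)
  switch(method,
         "none" = expr,
         "center-genes" = expression_matrix(expr$values - rowMeans(expr$values),
                                            expr$gene_ids, expr$sample_ids),
         "z-score-genes" = zscore_genes(expr))
}
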