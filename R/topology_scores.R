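# Expression-independent network quality scores. Both scores ask whether
# coregulated gene pairs (genes whose regulator sets have Jaccard
# similarity above a threshold) are enriched for an independent signal:
# protein-protein interactions, or shared specific GO annotation.

#' Coregulated gene pairs of a network
#'
#' Two genes are coregulated when the Jaccard similarity of their TF
#' regulator sets strictly exceeds `jaccard_min`. Genes without regulators
#' participate in no pair.
#'
#' @param net a [grn_edge_set()].
#' @param jaccard_min similarity threshold (default 0.5, strict).
#' @return data.frame with columns `gene_a`, `gene_b` (`gene_a < gene_b`)
#'   and `jaccard`.
#' @export
coregulated_pairs <- function(net, jaccard_min = 0.5) {
  inc <- sparsify(net) != 0             # genes x TFs incidence
  deg <- Matrix::rowSums(inc)
  genes <- net$gene_ids[deg > 0]
  if (length(genes) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      jaccard = double()))
  }
  inc <- inc[deg > 0, , drop = FALSE]
  deg <- deg[deg > 0]
  inter <- as.matrix(Matrix::tcrossprod(inc * 1))
  uni <- outer(deg, deg, "+") - inter
  jac <- inter / uni
  idx <- which(upper.tri(jac) & jac > jaccard_min, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      jaccard = double()))
  }
  a <- genes[idx[, 1]]; b <- genes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  data.frame(gene_a = a[ord], gene_b = b[ord],
             jaccard = jac[idx][ord], row.names = NULL)
}

#' Hypergeometric enrichment as -log10(p)
#'
#' Upper-tail probability `P(X >= n_hits)` for
#' `X ~ Hypergeom(n_universe, n_marked, n_draws)`, computed in log space
#' ([stats::phyper()]) so extreme enrichments do not underflow, and
#' returned as `-log10(p)`.
#'
#' @param n_hits observed marked draws.
#' @param n_draws draws taken.
#' @param n_marked marked elements in the universe.
#' @param n_universe universe size.
#' @return non-negative `-log10(p)`; 0 when `n_hits = 0`.
#' @export
hypergeom_enrichment <- function(n_hits, n_draws, n_marked, n_universe) {
  stopifnot(n_hits >= 0, n_draws >= n_hits, n_universe >= n_draws,
            n_marked >= 0, n_universe >= n_marked)
  if (n_hits > n_marked) stop("n_hits cannot exceed n_marked")
  if (n_hits == 0) return(0)
  logp <- stats::phyper(n_hits - 1, n_marked, n_universe - n_marked, n_draws,
                        lower.tail = FALSE, log.p = TRUE)
  -logp / log(10)
}

#' PPI enrichment score of a network
#'
#' Hypergeometric test of whether the network's coregulated gene pairs are
#' enriched in protein-protein interactions. The universe is all unordered
#' pairs among genes that (i) have at least one regulator in the network
#' and (ii) appear in the PPI gene set. With M such pairs, N of them PPIs,
#' m coregulated pairs and n coregulated PPI pairs, the score is
#' `-log10 P(X >= n)` for `X ~ Hypergeom(M, N, m)`.
#'
#' The score is meaningless for sparse networks with few coregulated
#' pairs; `m = 0` returns 0 with a warning.
#'
#' @param net a [grn_edge_set()].
#' @param ppi_pairs data.frame with columns `gene_a`, `gene_b` (undirected,
#'   deduplicated; see [read_ppi_pairs()]).
#' @param jaccard_min coregulation threshold.
#' @return `-log10(p)` enrichment score.
#' @export
ppi_score <- function(net, ppi_pairs, jaccard_min = 0.5) {
  inc <- sparsify(net) != 0
  reg_genes <- net$gene_ids[Matrix::rowSums(inc) > 0]
  ppi_genes <- unique(c(ppi_pairs$gene_a, ppi_pairs$gene_b))
  universe_genes <- intersect(reg_genes, ppi_genes)
  n_u <- length(universe_genes)
  if (n_u < 2L) {
    warning("fewer than 2 scorable genes; PPI score undefined, returning 0")
    return(0)
  }
  M <- n_u * (n_u - 1) / 2
  pk <- pair_key(ppi_pairs$gene_a, ppi_pairs$gene_b)
  in_univ <- ppi_pairs$gene_a %in% universe_genes &
    ppi_pairs$gene_b %in% universe_genes
  ppi_keys <- unique(pk[in_univ])
  N <- length(ppi_keys)
  co <- coregulated_pairs(net, jaccard_min)
  co <- co[co$gene_a %in% universe_genes & co$gene_b %in% universe_genes, ]
  m <- nrow(co)
  if (m == 0L) {
    warning("no coregulated pairs in the universe; ",
            "PPI score is not meaningful for sparse networks, returning 0")
    return(0)
  }
  n <- sum(pair_key(co$gene_a, co$gene_b) %in% ppi_keys)
  hypergeom_enrichment(n, m, N, M)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read an undirected PPI pair list
#'
#' TSV with two gene columns; pairs are deduplicated regardless of order
#' and self-pairs dropped.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ppi_pairs <- function(path) {
  dt <- read_tsv_optional_header(path, c("gene_a", "gene_b"))
  if (ncol(dt) < 2L) stop("PPI file needs two gene columns")
  a <- as.character(dt[[1]]); b <- as.character(dt[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  data.frame(gene_a = lo[!dup], gene_b = hi[!dup])
}

#' Build a GO-style annotation set
#'
#' @param gene,term parallel character vectors (many-to-many annotation).
#' @param term_roots named character vector mapping every term to its
#'   namespace root identifier (e.g. `"F"`, `"P"`, `"C"`). A term equal to
#'   its own root is a root term.
#' @return object of class `annotation_set` with per-gene term sets, term
#'   counts, and namespace (root) gene counts.
#' @export
annotation_set <- function(gene, term, term_roots) {
  gene <- as.character(gene); term <- as.character(term)
  stopifnot(length(gene) == length(term))
  terms <- unique(term)
  if (!all(terms %in% names(term_roots))) {
    stop("term without a declared namespace root: ",
         setdiff(terms, names(term_roots))[1])
  }
  dup <- duplicated(paste(gene, term, sep = "\r"))
  gene <- gene[!dup]; term <- term[!dup]
  gene2terms <- split(term, gene)
  term_count <- table(term)
  roots <- term_roots[terms]
  # |root| = number of distinct genes annotated anywhere in that namespace
  root_count <- tapply(gene, roots[term], function(g) length(unique(g)))
  structure(list(gene2terms = gene2terms,
                 term_count = as.list(term_count),
                 term_root = as.list(roots),
                 root_count = as.list(root_count)),
            class = "annotation_set")
}

#' Read annotations from a two-column TSV plus a roots sidecar
#'
#' @param path TSV `gene<TAB>term`.
#' @param roots_path YAML mapping each term (or term prefix rule) to a
#'   namespace root: a named map `term: root`.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, roots_path) {
  dt <- read_tsv_optional_header(path, c("gene", "term"))
  if (ncol(dt) < 2L) stop("annotation file needs columns gene, term")
  roots <- unlist(yaml::read_yaml(roots_path))
  annotation_set(dt[[1]], dt[[2]], roots)
}

#' Information content of an annotation term
#'
#' `IC(g) = -ln(|g| / |root(g)|)` with `|g|` the number of genes annotated
#' to the term and `|root|` the number of genes annotated in the term's
#' namespace. Root terms have IC 0 by definition.
#'
#' @param term a term identifier present in `annot`.
#' @param annot an [annotation_set()].
#' @return non-negative information content (natural log).
#' @export
information_content <- function(term, annot) {
  if (is.null(annot$term_count[[term]])) stop("unknown term: ", term)
  root <- annot$term_root[[term]]
  if (identical(term, root)) return(0)
  nroot <- annot$root_count[[root]]
  if (is.null(nroot) || nroot == 0) stop("empty namespace root: ", root)
  -log(annot$term_count[[term]] / nroot)
}

#' GO coherence score of a network
#'
#' Like [ppi_score()] but the independent signal is shared specific
#' function: each gene's annotation is filtered to terms with information
#' content above `ic_min`, a pair is functionally similar when the Jaccard
#' similarity of the filtered term sets strictly exceeds `jaccard_min`, and
#' the score is the hypergeometric enrichment of functionally similar
#' pairs among coregulated pairs. The universe is all pairs of genes that
#' have a regulator and at least one retained term.
#'
#' @param net a [grn_edge_set()].
#' @param annot an [annotation_set()].
#' @param ic_min information-content filter (default 2).
#' @param jaccard_min similarity threshold for both coregulation and
#'   functional similarity.
#' @return `-log10(p)` enrichment score.
#' @export
go_score <- function(net, annot, ic_min = 2, jaccard_min = 0.5) {
  ic <- vapply(names(annot$term_count), information_content, numeric(1),
               annot = annot)
  kept_terms <- names(ic)[ic > ic_min]
  filt <- lapply(annot$gene2terms, function(ts) intersect(ts, kept_terms))
  filt <- filt[vapply(filt, length, integer(1)) > 0]
  inc <- sparsify(net) != 0
  reg_genes <- net$gene_ids[Matrix::rowSums(inc) > 0]
  universe_genes <- intersect(reg_genes, names(filt))
  if (length(universe_genes) < 2L) {
    warning("fewer than 2 annotated regulated genes after the IC filter; ",
            "GO score undefined, returning 0")
    return(0)
  }
  n_u <- length(universe_genes)
  M <- n_u * (n_u - 1) / 2
  # functionally similar pairs among the universe
  sim_keys <- character(0)
  for (i in seq_len(n_u - 1L)) {
    gi <- universe_genes[i]
    ti <- filt[[gi]]
    for (j in seq((i + 1L), n_u)) {
      gj <- universe_genes[j]
      tj <- filt[[gj]]
      jac <- length(intersect(ti, tj)) / length(union(ti, tj))
      if (jac > jaccard_min) sim_keys <- c(sim_keys, pair_key(gi, gj))
    }
  }
  N <- length(sim_keys)
  co <- coregulated_pairs(net, jaccard_min)
  co <- co[co$gene_a %in% universe_genes & co$gene_b %in% universe_genes, ]
  m <- nrow(co)
  if (m == 0L) {
    warning("no coregulated pairs in the universe; GO score returning 0")
    return(0)
  }
  n <- sum(pair_key(co$gene_a, co$gene_b) %in% sim_keys)
  hypergeom_enrichment(n, m, N, M)
}
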