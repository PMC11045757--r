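#' Call genetic dependencies from a gene-effect matrix
#'
#' A gene is a dependency when its Chronos-style gene-effect score is
#' strictly below `threshold` in at least `min_lines` cell lines (the
#' ">2/7 lines" rule with the default seven-line panel means >= 3). `NA`
#' scores are ignored per line.
#'
#' @param scores Gene-by-line numeric matrix with row names.
#' @param threshold Score cutoff, strict inequality (default -0.5).
#' @param min_lines Minimum number of lines below threshold (default 3).
#' @return Character vector of dependency gene ids.
#' @export
call_dependencies <- function(scores, threshold = -0.5, min_lines = 3) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0 || ncol(scores) == 0) stop("empty score matrix")
  if (min_lines > ncol(scores))
    stop("min_lines exceeds the number of cell lines")
  hits <- rowSums(scores < threshold, na.rm = TRUE)
  rownames(scores)[hits >= min_lines]
}

#' Overlap of a query gene set with a dependency set
#'
#' @param query Non-empty character vector of query genes (e.g. genes
#'   downregulated by a compound).
#' @param dependency_set Character vector of dependency genes.
#' @return List with `n_query`, `n_overlap`, `fraction`
#'   (= |query intersect dependency| / |query|) and `counts`
#'   (overlap, non-overlap) for 2x2 construction.
#' @export
overlap_fraction <- function(query, dependency_set) {
  query <- unique(query)
  if (length(query) == 0) stop("empty query set")
  ov <- length(intersect(query, dependency_set))
  list(n_query = length(query), n_overlap = ov,
       fraction = ov / length(query),
       counts = c(overlap = ov, no_overlap = length(query) - ov))
}

#' Compare two overlap fractions by Fisher exact test
#'
#' Builds the 2x2 table of (in dependency set, not in dependency set) counts
#' for two query sets and returns the two-sided exact p-value, as used to
#' compare the dependency content of different compounds' downregulated
#' genes.
#'
#' @param a,b Results of [overlap_fraction()].
#' @return List with `table` and `p`.
#' @export
compare_overlaps <- function(a, b) {
  tab <- rbind(a$counts, b$counts)
  list(table = tab, p = fisher_two_sided(tab))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value with the probability-ordering two-sided rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (within relative
#' tolerance 1e-7 to avoid floating-point ties). A zero margin returns
#' p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided exact p-value.
#' @export
fisher_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); N <- sum(table)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) {
    warning("zero margin; p = 1 by convention")
    return(1)
  }
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(table[1, 1], c1, N - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Connectivity of a gene set in an interaction graph
#'
#' Induces the subgraph of `genes` on the confidence-filtered edge list and
#' summarizes its connectivity; genes absent from the graph vocabulary count
#' as isolated nodes. A permutation null (size-matched random gene sets
#' drawn from the graph vocabulary) yields a z-score for the induced edge
#' count.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `confidence`
#'   in [0, 1]; undirected, no self-loops.
#' @param genes Non-empty character vector of query genes.
#' @param min_confidence Minimum edge confidence retained (default 0.4,
#'   medium confidence).
#' @param n_perm Number of permutation null sets (default 200).
#' @param seed Seed for the permutation draws.
#' @return List with `n_genes`, `n_edges`, `mean_degree`, `frac_connected`
#'   (genes with >= 1 induced edge), `frac_largest_component`, `perm_z`,
#'   `perm_mean`, `perm_sd`.
#' @export
subgraph_stats <- function(edges, genes, min_confidence = 0.4,
                           n_perm = 200, seed = 1L) {
  genes <- unique(genes)
  if (length(genes) == 0) stop("empty gene set")
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  if (any(edges$confidence < 0 | edges$confidence > 1))
    stop("confidence outside [0, 1]")
  if (any(edges$gene_a == edges$gene_b)) stop("self-loop in edge list")
  edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  vocab <- unique(c(edges$gene_a, edges$gene_b))
  g <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                     directed = FALSE, vertices = vocab)

  count_edges <- function(set) {
    sub <- igraph::induced_subgraph(g, intersect(set, vocab))
    igraph::ecount(sub)
  }
  sub <- igraph::induced_subgraph(g, intersect(genes, vocab))
  m <- igraph::ecount(sub)
  deg <- igraph::degree(sub)
  n_connected <- sum(deg >= 1)
  comp <- if (igraph::vcount(sub) > 0) igraph::components(sub) else NULL
  largest <- if (is.null(comp)) 0 else max(comp$csize)

  set.seed(seed)
  k <- min(length(genes), length(vocab))
  perm <- replicate(n_perm, count_edges(sample(vocab, k)))
  psd <- stats::sd(perm)
  z <- if (is.na(psd) || psd == 0) NA_real_ else (m - mean(perm)) / psd

  list(n_genes = length(genes), n_edges = m,
       mean_degree = 2 * m / length(genes),
       frac_connected = n_connected / length(genes),
       frac_largest_component = largest / length(genes),
       perm_z = z, perm_mean = mean(perm), perm_sd = psd)
}
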