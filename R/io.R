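#' Read a long-format screen viability TSV
#'
#' Expected columns: `cell_line`, `lineage`, `compound`, `dose_molar`,
#' `viability`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return data.frame suitable for [compute_auc_table()].
#' @export
read_screen_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "lineage", "compound", "dose_molar", "viability")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read a count matrix TSV
#'
#' First column = row ids (genes / spike-ins), remaining columns = samples.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Integer matrix with row and column names.
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "numeric"
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}

#' Read a gene-effect (dependency) matrix CSV
#'
#' Genes in the first column, cell lines as the header row.
#'
#' @param path Path to a CSV file.
#' @return Numeric matrix genes x lines.
#' @export
read_dependency_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "numeric"
  m
}

#' Read an interaction edge list TSV
#'
#' Expected columns: `gene_a`, `gene_b`, `confidence`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return data.frame suitable for [subgraph_stats()].
#' @export
read_edge_list <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "confidence")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (set name, description, tab-separated
#'   gene ids per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a gene set as one id per line
#'
#' @param genes Character vector.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
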