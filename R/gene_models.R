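#' Exon-union length of one gene
#'
#' Length of the union of all exon intervals across all isoforms of a gene,
#' with overlapping exons merged and duplicates ignored. Coordinates are
#' 1-based inclusive (GTF convention); strand is irrelevant to length.
#'
#' @param starts,ends Integer vectors of exon starts and ends (1-based,
#'   inclusive), one entry per exon across all isoforms.
#' @return Total merged length in bp.
#' @export
exon_union_length <- function(starts, ends) {
  if (length(starts) == 0) stop("gene has no exons")
  if (length(starts) != length(ends)) stop("starts/ends lengths differ")
  if (any(starts > ends)) stop("malformed interval: start > end")
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
}

#' Exon-union lengths for a table of exons
#'
#' @param exons data.frame with columns `gene_id`, `start`, `end`
#'   (1-based inclusive; all exons of all isoforms).
#' @return Named numeric vector of per-gene exon-union lengths.
#' @export
exon_union_lengths <- function(exons) {
  need <- c("gene_id", "start", "end")
  if (!all(need %in% names(exons)))
    stop("exons must have columns: ", paste(need, collapse = ", "))
  vapply(split(exons[c("start", "end")], exons$gene_id),
         function(d) exon_union_length(d$start, d$end), numeric(1))
}

#' Read exon intervals from a GTF file
#'
#' Imports `exon` features and returns the per-gene exon table consumed by
#' [exon_union_lengths()].
#'
#' @param path Path to a GTF file with `gene_id` attributes.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_exons_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  data.frame(gene_id = gr$gene_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
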