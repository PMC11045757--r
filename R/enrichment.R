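#' Hypergeometric gene-set over-representation
#'
#' For each set in a collection, the exact upper tail
#' `P(X >= overlap)` under hypergeometric(|universe|, |set|, |query|),
#' i.e. the one-sided Fisher tail of the corresponding 2x2 table, with
#' BH adjustment across sets. An in-repo stand-in for remote
#' over-representation services.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); each set is intersected with the universe.
#' @param universe Character vector of all testable genes.
#' @return data.frame with `set`, `n_set`, `n_query`, `n_overlap`, `p`,
#'   `padj`, ordered by p.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes outside the universe")
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(query, s))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, length(s), length(universe) - length(s),
                    length(query), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(s), n_query = length(query),
               n_overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Count consensus-motif matches in promoter sequences
#'
#' Sliding-window counts of matches to an IUPAC consensus (default the
#' E-box CACGTG, the canonical MYC/MAX binding sequence). With
#' `both_strands`, reverse-complement matches are added, but a window that
#' matches on both strands -- as any palindromic motif does everywhere --
#' is counted once. Overlapping matches count separately.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`
#'   over A/C/G/T/N.
#' @param motif IUPAC consensus string (default "CACGTG").
#' @param both_strands Also scan the reverse strand (default TRUE).
#' @return Named integer vector of per-sequence match counts.
#' @export
motif_scan <- function(sequences, motif = "CACGTG", both_strands = TRUE) {
  if (is.character(sequences)) {
    bad <- grepl("[^ACGTNacgtn]", sequences)
    if (any(bad))
      stop("invalid characters in record(s): ",
           paste(utils::head(names(sequences)[bad], 5), collapse = ", "))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (!grepl("^[ACGTUWSMKRYBDHVN]+$", toupper(motif)))
    stop("motif is not an IUPAC DNA string")
  fwd <- Biostrings::DNAString(toupper(motif))
  rev <- Biostrings::reverseComplement(fwd)
  fixed <- c(pattern = FALSE, subject = TRUE)
  count_one <- function(seq) {
    f <- Biostrings::start(Biostrings::matchPattern(fwd, seq,
                                                    fixed = fixed))
    if (!both_strands) return(length(f))
    r <- Biostrings::start(Biostrings::matchPattern(rev, seq,
                                                    fixed = fixed))
    length(union(f, r))
  }
  out <- vapply(seq_along(sequences),
                function(i) count_one(sequences[[i]]), integer(1))
  names(out) <- names(sequences)
  out
}

#' Motif enrichment of query promoters against a background
#'
#' Dichotomizes promoters as motif-positive (>= 1 match) or negative and
#' compares query against background with the two-sided Fisher exact test.
#' Records present in both inputs are excluded from the background.
#'
#' @param query_promoters,background_promoters Named character vectors or
#'   `DNAStringSet`s of promoter sequences.
#' @param motif IUPAC consensus (default "CACGTG").
#' @param both_strands Scan both strands (default TRUE).
#' @return List with `table` (2x2: query/background x positive/negative),
#'   `p`, `frac_query`, `frac_background`.
#' @export
motif_enrichment <- function(query_promoters, background_promoters,
                             motif = "CACGTG", both_strands = TRUE) {
  if (length(query_promoters) == 0 || length(background_promoters) == 0)
    stop("empty promoter set")
  qn <- names(query_promoters); bn <- names(background_promoters)
  if (!is.null(qn) && !is.null(bn) && length(intersect(qn, bn)) > 0) {
    message("excluding ", length(intersect(qn, bn)),
            " query record(s) from the background")
    background_promoters <- background_promoters[setdiff(bn, qn)]
    if (length(background_promoters) == 0)
      stop("background empty after excluding query records")
  }
  q <- motif_scan(query_promoters, motif, both_strands) > 0
  b <- motif_scan(background_promoters, motif, both_strands) > 0
  tab <- rbind(query = c(positive = sum(q), negative = sum(!q)),
               background = c(positive = sum(b), negative = sum(!b)))
  list(table = tab, p = fisher_two_sided(tab),
       frac_query = mean(q), frac_background = mean(b))
}
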