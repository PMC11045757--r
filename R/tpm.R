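#' Transcripts-per-million from raw counts
#'
#' Per sample: `rate_g = count_g * read_length / length_g`,
#' `normterm = sum_g(rate_g)`, `TPM_g = rate_g * 1e6 / normterm`.
#' The read length cancels within a sample but is retained in the formula;
#' spike-in rows use their reference sequence lengths and contribute to
#' `normterm` like any other row. Column sums equal 1e6.
#'
#' @param counts Non-negative count matrix with unique row names (genes and
#'   spike-ins) and sample columns.
#' @param lengths Named vector of per-row lengths in bp, covering every row.
#' @param read_length Read length in bp (default 100).
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, lengths, read_length = 100) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have row names")
  if (anyDuplicated(rownames(counts))) stop("duplicate row ids")
  if (any(counts < 0)) stop("negative counts")
  if (read_length <= 0) stop("read_length must be > 0")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0)
    stop("no length for row(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("lengths must be positive")
  rate <- counts * read_length / len
  normterm <- colSums(rate)
  if (any(normterm == 0)) stop("sample with all-zero counts")
  sweep(rate, 2, normterm, "/") * 1e6
}

#' Spike-in anchored MA-loess normalization
#'
#' Removes intensity-dependent between-sample bias by fitting, for each
#' sample, a loess curve of M = log2(sample) - log2(reference) against
#' A = (log2(sample) + log2(reference))/2 on spike-in rows only, and
#' subtracting the fitted curve from all rows. The reference is the per-row
#' mean of log2 TPM across samples (a geometric-mean pseudo-reference), so
#' the result does not depend on sample order. Because only spike-ins --
#' whose true abundance is fixed per cell -- inform the fit, a global shift
#' of endogenous transcription is preserved rather than normalized away.
#'
#' A pseudocount is added before the log and removed after
#' back-transformation; the fitted curve is extended as a constant beyond
#' the spike-in A-range.
#'
#' @param tpm TPM matrix (rows include spike-ins, identified by
#'   `spikein_ids`).
#' @param spikein_ids Row ids of spike-in controls; at least 8 must have
#'   positive values in every sample.
#' @param span Loess span (default 0.5).
#' @param degree Local polynomial degree (default 2).
#' @param iterations Robustifying iterations of the symmetric family
#'   (default 4).
#' @param pseudocount Added before log2 (default 0.5).
#' @return Normalized matrix of the same shape, on the TPM scale.
#' @export
loess_normalize <- function(tpm, spikein_ids, span = 0.5, degree = 2,
                            iterations = 4, pseudocount = 0.5) {
  tpm <- as.matrix(tpm)
  spike <- intersect(rownames(tpm), spikein_ids)
  n_ok <- sum(apply(tpm[spike, , drop = FALSE] > 0, 1, all))
  if (n_ok < 8)
    stop("need >= 8 spike-in rows with positive values in every sample; ",
         "found ", n_ok)
  l <- log2(tpm + pseudocount)
  ref <- rowMeans(l)
  si <- rownames(tpm) %in% spike
  out <- l
  for (s in seq_len(ncol(l))) {
    M <- l[, s] - ref
    A <- (l[, s] + ref) / 2
    # a constant spike-in M (identical or globally scaled sample) needs no
    # curve, and zero residual spread breaks the robust fit
    if (max(abs(M[si] - mean(M[si]))) < 1e-10) {
      out[, s] <- l[, s] - mean(M[si])
      next
    }
    fit <- stats::loess(M ~ A, data = data.frame(A = A[si], M = M[si]),
                        span = span, degree = degree,
                        family = "symmetric",
                        control = stats::loess.control(
                          iterations = iterations, surface = "direct"))
    A_eval <- pmin(pmax(A, min(A[si])), max(A[si]))
    out[, s] <- l[, s] - stats::predict(fit, newdata = data.frame(A = A_eval))
  }
  pmax(2^out - pseudocount, 0)
}
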