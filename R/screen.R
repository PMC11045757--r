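#' Dose-response area under the curve
#'
#' Summarizes a fraction-of-control viability series as the trapezoidal
#' integral of viability over log10(dose), divided by the log10-dose range,
#' so a fully unaffected line scores exactly 1 and a fully killed line 0.
#' Viability is clipped to [0, `cap`] first to bound growth-stimulation
#' artifacts. An optional four-parameter logistic fit (`method = "4pl"`)
#' integrates the fitted Hill curve instead of the raw points.
#'
#' @param doses Strictly increasing positive molar doses (>= 2).
#' @param viability Non-negative fraction-of-control viabilities, same
#'   length as `doses`.
#' @param cap Upper viability clip (default 1.2).
#' @param method `"trapezoid"` (default) or `"4pl"`.
#' @return Scalar AUC, unitless.
#' @export
compute_auc <- function(doses, viability, cap = 1.2,
                        method = c("trapezoid", "4pl")) {
  method <- match.arg(method)
  if (length(doses) < 2) stop("need at least 2 doses")
  if (length(doses) != length(viability))
    stop("doses and viability lengths differ")
  if (any(!is.finite(viability))) stop("non-finite viability")
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  v <- pmin(pmax(viability, 0), cap)
  x <- log10(doses)
  if (method == "trapezoid") {
    auc <- sum(diff(x) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
    return(auc / diff(range(x)))
  }
  # 4PL: v = floor + (top - floor) / (1 + 10^(slope * (x - log10(ic50))))
  fit <- tryCatch(suppressWarnings(
    stats::nls(v ~ fl + (tp - fl) / (1 + 10^(sl * (x - xmid))),
               start = list(fl = min(v), tp = max(v), sl = 1,
                            xmid = stats::median(x)),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) stop("4PL fit failed; use method = 'trapezoid'")
  f <- function(xx) pmin(pmax(stats::predict(fit,
                                             newdata = data.frame(x = xx)),
                              0), cap)
  stats::integrate(f, min(x), max(x))$value / diff(range(x))
}

#' Per-compound median normalization
#'
#' Divides each value by the median of the vector so the normalized median
#' is exactly 1; the even-count median is the mean of the two central order
#' statistics. This makes AUCs comparable between screens run
#' non-simultaneously and leaves per-line ratios invariant to global scale.
#'
#' @param x Numeric vector with at least one finite value.
#' @return `x / median(x)`.
#' @export
median_normalize <- function(x) {
  if (!any(is.finite(x))) stop("need at least one finite value")
  m <- stats::median(x, na.rm = TRUE)
  if (m == 0) stop("median is zero; degenerate screen")
  x / m
}

#' AUC table for a long-format screen
#'
#' Computes the raw AUC per (cell line, compound) series and the
#' median-normalized AUC within each compound.
#'
#' @param screen Long data.frame with columns `cell_line`, `lineage`,
#'   `compound`, `dose_molar`, `viability`.
#' @param cap,method Passed to [compute_auc()].
#' @return data.frame with `cell_line`, `lineage`, `compound`, `raw_auc`,
#'   `norm_auc`.
#' @export
compute_auc_table <- function(screen, cap = 1.2, method = "trapezoid") {
  need <- c("cell_line", "lineage", "compound", "dose_molar", "viability")
  if (!all(need %in% names(screen)))
    stop("screen must have columns: ", paste(need, collapse = ", "))
  key <- interaction(screen$cell_line, screen$compound, drop = TRUE)
  parts <- split(screen, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$dose_molar), ]
    data.frame(cell_line = d$cell_line[1], lineage = d$lineage[1],
               compound = d$compound[1],
               raw_auc = compute_auc(d$dose_molar, d$viability, cap = cap,
                                     method = method),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$norm_auc <- NA_real_
  for (cmp in unique(out$compound)) {
    i <- out$compound == cmp
    out$norm_auc[i] <- median_normalize(out$raw_auc[i])
  }
  out
}

#' Classify a normalized AUC ratio
#'
#' A ratio of BRD-inhibitor over HAT-inhibitor normalized AUC above `hi`
#' marks a line as relatively more affected by the HAT inhibitor
#' (`hat_preferential`); below `lo`, by the BRD inhibitor
#' (`brd_preferential`). Inequalities are strict, so a ratio exactly at a
#' threshold is `neutral`.
#'
#' @param ratio Positive numeric vector of normalized AUC ratios (BRD/HAT).
#' @param hi,lo Thresholds (defaults 1.2 and 0.8).
#' @return Character vector of classes.
#' @export
classify_ratio <- function(ratio, hi = 1.2, lo = 0.8) {
  stopifnot(lo < hi)
  if (any(ratio <= 0, na.rm = TRUE)) stop("ratio must be > 0")
  out <- rep("neutral", length(ratio))
  out[ratio > hi] <- "hat_preferential"
  out[ratio < lo] <- "brd_preferential"
  out[is.na(ratio)] <- NA_character_
  out
}

#' Per-line ratio of median-normalized AUCs
#'
#' Matches cell lines between the two compounds' normalized AUC vectors and
#' returns the per-line BRD/HAT ratio with its classification. Lines present
#' for only one compound are dropped with a warning; lines whose HAT
#' normalized AUC is zero are flagged invalid and excluded.
#'
#' @param norm_brd,norm_hat Named numeric vectors of median-normalized AUCs
#'   (names = cell lines) for the BRD- and HAT-targeting compounds.
#' @param hi,lo Classification thresholds, see [classify_ratio()].
#' @return data.frame with `cell_line`, `ratio`, `class`.
#' @export
compute_ratio_table <- function(norm_brd, norm_hat, hi = 1.2, lo = 0.8) {
  if (is.null(names(norm_brd)) || is.null(names(norm_hat)))
    stop("norm_brd and norm_hat must be named by cell line")
  shared <- intersect(names(norm_brd), names(norm_hat))
  dropped <- setdiff(union(names(norm_brd), names(norm_hat)), shared)
  if (length(dropped) > 0)
    warning(length(dropped), " line(s) present for only one compound ",
            "dropped: ", paste(utils::head(dropped, 5), collapse = ", "))
  if (length(shared) == 0) stop("no shared cell lines")
  b <- norm_brd[shared]
  h <- norm_hat[shared]
  bad <- h == 0
  if (any(bad)) {
    warning(sum(bad), " line(s) with zero HAT normalized AUC excluded")
    shared <- shared[!bad]; b <- b[!bad]; h <- h[!bad]
  }
  ratio <- b / h
  data.frame(cell_line = shared, ratio = unname(ratio),
             class = classify_ratio(ratio, hi = hi, lo = lo),
             stringsAsFactors = FALSE)
}

#' Collapse ratio records into lineage summaries
#'
#' Groups per-line AUC ratios by lineage, reports the per-lineage median
#' ratio, and excludes lineages represented by fewer than `min_n` lines
#' (their lines are not counted in the retained total).
#'
#' @param ratios data.frame with `cell_line` and `ratio` (as returned by
#'   [compute_ratio_table()]).
#' @param lineage_map Named character vector mapping every cell line to a
#'   lineage.
#' @param min_n Minimum lines per retained lineage (default 3).
#' @return List with `summary` (data.frame: `lineage`, `n_lines`,
#'   `median_ratio`, `retained`) and `n_retained_lines`, the total number of
#'   lines in retained lineages.
#' @export
summarize_lineages <- function(ratios, lineage_map, min_n = 3) {
  unmapped <- setdiff(ratios$cell_line, names(lineage_map))
  if (length(unmapped) > 0)
    stop("unmapped cell line(s): ", paste(unmapped, collapse = ", "))
  lin <- lineage_map[ratios$cell_line]
  summ <- do.call(rbind, lapply(split(ratios$ratio, lin), function(r) {
    data.frame(n_lines = length(r), median_ratio = stats::median(r))
  }))
  summ <- data.frame(lineage = rownames(summ), summ,
                     stringsAsFactors = FALSE, row.names = NULL)
  summ$retained <- summ$n_lines >= min_n
  summ <- summ[order(summ$median_ratio), ]
  rownames(summ) <- NULL
  list(summary = summ[summ$retained, ],
       all_lineages = summ,
       n_retained_lines = sum(summ$n_lines[summ$retained]))
}

#' Squared Pearson correlation between two AUC vectors
#'
#' @param x,y Numeric vectors; pairs with a non-finite member are dropped;
#'   at least 3 complete pairs required.
#' @return Scalar R-squared.
#' @export
pairwise_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 paired finite values")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input vector")
  stats::cor(x, y)^2
}
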