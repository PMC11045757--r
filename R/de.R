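#' Size factors from control (spike-in) rows
#'
#' Median-of-ratios estimator restricted to control rows: for sample s,
#' `factor_s = median_g(count_gs / geomean_g)` over control rows g whose
#' counts are positive in every sample (the geometric mean is undefined at
#' zero). Factors are rescaled so their geometric mean is 1. Anchoring on
#' external controls of fixed per-cell abundance makes the factors estimate
#' technical depth only, so genuine global shifts in endogenous
#' transcription survive normalization.
#'
#' @param counts Count matrix with row names.
#' @param control_ids Row ids of the control (spike-in) rows.
#' @return Named per-sample size-factor vector, geometric mean 1.
#' @export
control_gene_size_factors <- function(counts, control_ids) {
  counts <- as.matrix(counts)
  ctrl <- counts[intersect(rownames(counts), control_ids), , drop = FALSE]
  ctrl <- ctrl[apply(ctrl > 0, 1, all), , drop = FALSE]
  if (nrow(ctrl) == 0)
    stop("no control rows with nonzero counts in all samples")
  if (nrow(ctrl) < 8)
    warning("only ", nrow(ctrl), " eligible control rows; ",
            "size factors may be unstable")
  logratio <- log(ctrl) - rowMeans(log(ctrl))
  f <- exp(apply(logratio, 2, stats::median))
  f / exp(mean(log(f)))
}

#' Library-size (total-count) size factors
#'
#' Per-sample column totals rescaled to geometric mean 1. Provided as the
#' naive alternative to [control_gene_size_factors()]: when treatment shifts
#' endogenous transcription globally, total-count factors absorb part of the
#' shift and misattribute change to unaffected rows.
#'
#' @param counts Count matrix.
#' @return Named per-sample size-factor vector, geometric mean 1.
#' @export
library_size_factors <- function(counts) {
  tot <- colSums(as.matrix(counts))
  if (any(tot == 0)) stop("sample with zero total count")
  tot / exp(mean(log(tot)))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments gene-wise estimates on size-factor-normalized counts,
#' `alpha_hat = max(floor, (s^2 - mu) / mu^2)`, where the variance pools
#' within-condition deviations when `condition` is supplied (so planted
#' between-condition differences do not inflate dispersion). A mean-
#' dispersion trend `alpha_tr(mu) = a0 + a1/mu` is fit by least squares over
#' genes with `mu >= trend_min_mu` and an above-floor gene-wise estimate
#' (one outlier-trimmed refit), and the final dispersion blends the two on
#' the log scale: `exp(w*log(alpha_tr) + (1-w)*log(alpha_hat))`. Gene-wise
#' estimates at the floor are blended from the trend downward rather than
#' from the floor itself, which would otherwise collapse the blend to a
#' near-Poisson model for genes whose moment estimate is zero by sampling
#' noise.
#'
#' @param counts Count matrix.
#' @param size_factors Per-sample size factors.
#' @param condition Optional factor of per-sample conditions; each level
#'   must have >= 2 samples.
#' @param floor Minimum dispersion (default 1e-8).
#' @param trend_min_mu Minimum normalized mean for genes entering the trend
#'   fit (default 5).
#' @param shrink_weight Trend-blend weight w in [0, 1] (default 0.5).
#' @return List with `alpha` (final per-gene dispersions), `alpha_mom`
#'   (gene-wise estimates), `alpha_trend` (trend values), `trend` (a0, a1)
#'   and `mu` (normalized means).
#' @export
estimate_dispersions <- function(counts, size_factors, condition = NULL,
                                 floor = 1e-8, trend_min_mu = 5,
                                 shrink_weight = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(size_factors),
            shrink_weight >= 0, shrink_weight <= 1)
  norm <- sweep(counts, 2, size_factors, "/")
  if (!is.null(condition)) {
    condition <- as.factor(condition)
    if (any(table(condition) < 2))
      stop("each condition needs at least 2 samples")
    ctr <- norm
    for (lev in levels(condition)) {
      j <- condition == lev
      ctr[, j] <- norm[, j] - rowMeans(norm[, j, drop = FALSE])
    }
    df <- ncol(norm) - nlevels(condition)
    s2 <- rowSums(ctr^2) / df
  } else {
    if (ncol(counts) < 2) stop("need at least 2 samples")
    s2 <- apply(norm, 1, stats::var)
  }
  mu <- rowMeans(norm)
  mom <- (s2 - mu) / mu^2
  mom[!is.finite(mom)] <- NA
  alpha_mom <- pmax(floor, mom)

  use <- is.finite(mom) & mu >= trend_min_mu & mom > floor
  a0 <- 0.01; a1 <- 1
  if (sum(use) >= 10) {
    fit <- stats::lm(mom[use] ~ I(1 / mu[use]))
    resid_ratio <- mom[use] / pmax(stats::fitted(fit), floor)
    keep <- resid_ratio > 0.1 & resid_ratio < 10
    if (sum(keep) >= 10)
      fit <- stats::lm(mom[use][keep] ~ I(1 / mu[use][keep]))
    a0 <- max(unname(stats::coef(fit)[1]), 1e-6)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  }
  alpha_trend <- pmax(a0 + a1 / pmax(mu, 1e-8), floor)

  # genes whose MoM estimate collapsed to the floor carry no usable
  # gene-wise signal: take the trend value, not sqrt(floor * trend)
  blend_from <- ifelse(!is.na(alpha_mom) & alpha_mom > floor,
                       alpha_mom, alpha_trend)
  w <- shrink_weight
  alpha <- exp(w * log(alpha_trend) + (1 - w) * log(blend_from))
  alpha <- pmax(alpha, floor)
  # all-zero genes carry no information; give them the trend intercept so
  # downstream code sees a finite value (they are never tested anyway)
  alpha[mu == 0] <- a0
  names(alpha) <- rownames(counts)
  list(alpha = alpha, alpha_mom = alpha_mom, alpha_trend = alpha_trend,
       trend = c(a0 = a0, a1 = a1), mu = mu)
}

#' Wald tests from per-gene negative-binomial GLMs
#'
#' Fits, for each gene, an NB GLM with log link, design
#' intercept + condition, log size factors as offsets and the supplied
#' (fixed) dispersion; reports the condition coefficient as a log2 fold
#' change (treated vs control), its standard error, the Wald statistic from
#' observed Fisher information and a two-sided p-value. The p-value uses a
#' t reference with `n_samples - 2` degrees of freedom: with few replicates
#' the Wald ratio is noticeably heavier-tailed than normal (a normal
#' reference roughly doubles the nominal type-I error at 3 vs 3), and the t
#' reference converges to the normal one as replication grows. Genes with
#' all-zero counts get `NA` p-values and are excluded from the
#' multiple-testing denominator; non-converged fits are likewise flagged.
#'
#' @param counts Count matrix.
#' @param size_factors Per-sample size factors.
#' @param dispersions Per-gene dispersion vector (e.g.
#'   `estimate_dispersions(...)$alpha`).
#' @param treated,control Column names (or indices) of the treated and
#'   control samples; disjoint, each >= 2.
#' @param alpha Significance level on the BH-adjusted p for the `direction`
#'   call (default 0.05).
#' @return data.frame with `gene_id`, `base_mean`, `log2fc`, `se`, `wald`,
#'   `p`, `padj`, `direction` (up / down / ns).
#' @export
wald_test <- function(counts, size_factors, dispersions, treated, control,
                      alpha = 0.05) {
  counts <- as.matrix(counts)
  if (is.numeric(treated)) treated <- colnames(counts)[treated]
  if (is.numeric(control)) control <- colnames(counts)[control]
  if (length(intersect(treated, control)) > 0)
    stop("treated and control samples overlap")
  if (length(treated) < 2 || length(control) < 2)
    stop("need >= 2 samples per condition")
  cols <- c(control, treated)
  if (!all(cols %in% colnames(counts))) stop("unknown sample ids")
  sf <- size_factors[cols]
  cond <- factor(rep(c("control", "treated"), c(length(control),
                                                length(treated))),
                 levels = c("control", "treated"))
  off <- log(sf)
  disp <- dispersions[rownames(counts)]
  if (any(is.na(disp))) stop("dispersions missing for some genes")

  n <- nrow(counts)
  b <- se <- rep(NA_real_, n)
  base_mean <- rowMeans(sweep(counts[, cols, drop = FALSE], 2, sf, "/"))
  for (g in seq_len(n)) {
    y <- counts[g, cols]
    if (all(y == 0)) next
    theta <- min(1 / max(disp[g], 1e-8), 1e8)
    fit <- tryCatch(suppressWarnings(
      stats::glm(y ~ cond, offset = off,
                 family = MASS::negative.binomial(theta = theta,
                                                  link = "log"))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2) next
    b[g] <- cf[2, 1]
    se[g] <- cf[2, 2]
  }
  log2fc <- b / log(2)
  wald <- b / se
  p <- 2 * stats::pt(-abs(wald), df = length(cols) - 2)
  padj <- bh_adjust(p)
  direction <- rep("ns", n)
  sig <- !is.na(padj) & padj < alpha
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, se = se / log(2), wald = wald, p = p,
             padj = padj, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` entries are preserved and excluded from the
#' number of tests.
#'
#' @param p Vector of p-values in [0, 1], possibly with `NA`s.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' High-confidence cross-cell-line gene sets
#'
#' A gene enters the down set for a treatment when it is significant
#' (`padj < alpha`) with a negative log2 fold change in every supplied cell
#' line's result table; symmetrically for up. Genes significant everywhere
#' but with discordant directions are excluded. Mismatched gene universes
#' are intersected with a warning.
#'
#' @param results Named list (>= 2) of [wald_test()] result tables for the
#'   same contrast in different cell lines.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
high_confidence_sets <- function(results, alpha = 0.05) {
  if (length(results) < 2) stop("need result tables from >= 2 cell lines")
  universes <- lapply(results, function(r) r$gene_id)
  shared <- Reduce(intersect, universes)
  if (any(vapply(universes, length, 1L) != length(shared)))
    warning("gene universes differ between cell lines; intersecting")
  sig_up <- sig_down <- rep(TRUE, length(shared))
  for (r in results) {
    r <- r[match(shared, r$gene_id), ]
    s <- !is.na(r$padj) & r$padj < alpha
    sig_up <- sig_up & s & r$log2fc > 0
    sig_down <- sig_down & s & r$log2fc < 0
  }
  list(up = shared[sig_up], down = shared[sig_down])
}
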