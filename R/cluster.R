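#' Elbow point of a WSS curve
#'
#' Kneedle-style chord rule: the chosen k maximizes the perpendicular
#' distance from the (k, WSS) point to the chord joining the curve's
#' endpoints. A flat curve (WSS range below `flat_tol`) returns the smallest
#' k, since no elbow exists.
#'
#' @param k Integer vector of candidate k values (increasing).
#' @param wss Within-cluster sums of squares, same length as `k`.
#' @param flat_tol Range below which the curve counts as flat
#'   (default 1e-9).
#' @return The selected k.
#' @export
select_elbow <- function(k, wss, flat_tol = 1e-9) {
  stopifnot(length(k) == length(wss), length(k) >= 1)
  if (length(k) < 3 || diff(range(wss)) < flat_tol) return(k[1])
  x1 <- k[1]; y1 <- wss[1]
  x2 <- k[length(k)]; y2 <- wss[length(wss)]
  d <- abs((y2 - y1) * (k - x1) - (x2 - x1) * (wss - y1)) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  k[which.max(d)]
}

#' k-means clustering with elbow-based k selection
#'
#' Runs k-means for each candidate k, keeping the best of `restarts` seeded
#' random starts plus a warm start that splits the best (k-1)-solution at
#' its worst-fit point -- which guarantees the WSS curve is non-increasing
#' in k -- then picks k by the chord rule of [select_elbow()]. Rows are
#' standardized (mean 0, sd 1) by default, the usual convention for fold-
#' change heatmaps. Fully seed-deterministic.
#'
#' @param x Numeric matrix (rows = genes, columns = per-condition
#'   summaries, e.g. log2 fold changes); rows with non-finite values are
#'   dropped.
#' @param k_range Candidate k values (default 1:10).
#' @param restarts Random restarts per k (default 20).
#' @param seed Integer seed.
#' @param standardize Standardize rows before clustering (default TRUE).
#' @param tight_rms If the root-mean-square deviation of the (possibly
#'   standardized) matrix around its grand centroid is below this value,
#'   the data form a single tight cluster and k = 1 is returned without an
#'   elbow search (default 0.01, negligible on a log2 fold-change scale).
#' @return List with `k` (chosen), `assignments` (named by row), `wss`
#'   (named by k), `centers` for the chosen k, and `rows_used`.
#' @export
kmeans_elbow <- function(x, k_range = 1:10, restarts = 20, seed = 1L,
                         standardize = TRUE, tight_rms = 0.01) {
  x <- as.matrix(x)
  ok <- apply(is.finite(x), 1, all)
  x <- x[ok, , drop = FALSE]
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > nrow(x))
    stop("k_range must lie within [1, number of rows]")
  if (standardize) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    sdv[sdv == 0] <- 1
    x <- (x - mu) / sdv
  }

  run_k <- function(k, warm_centers) {
    best <- NULL
    if (k == 1) {
      ctr <- matrix(colMeans(x), 1, ncol(x))
      return(list(tot.withinss = sum(sweep(x, 2, ctr[1, ])^2),
                  cluster = stats::setNames(rep(1L, nrow(x)), rownames(x)),
                  centers = ctr))
    }
    starts <- vector("list", 0)
    if (!is.null(warm_centers) && nrow(warm_centers) + 1L == k) {
      # split previous solution at its worst-fit point
      prev_k <- nrow(warm_centers)
      d2 <- rowSums((x - warm_centers[attr(warm_centers, "cl"), ,
                                      drop = FALSE])^2)
      cand <- rbind(warm_centers, x[which.max(d2), , drop = FALSE])
      starts <- list(cand)
    }
    for (r in seq_len(restarts)) {
      set.seed(seed + 1009L * k + r)
      starts <- c(starts,
                  list(x[sample.int(nrow(x), k), , drop = FALSE]))
    }
    for (ctr in starts) {
      km <- tryCatch(suppressWarnings(
        stats::kmeans(x, centers = ctr, iter.max = 100)),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed for k = ", k)
    list(tot.withinss = best$tot.withinss,
         cluster = stats::setNames(best$cluster, rownames(x)),
         centers = best$centers)
  }

  fits <- vector("list", length(k_range))
  warm <- NULL
  for (i in seq_along(k_range)) {
    fits[[i]] <- run_k(k_range[i], warm)
    warm <- fits[[i]]$centers
    attr(warm, "cl") <- fits[[i]]$cluster
  }
  wss <- stats::setNames(vapply(fits, `[[`, numeric(1), "tot.withinss"),
                         k_range)
  tot_ss <- sum(sweep(x, 2, colMeans(x))^2)
  k_best <- if (sqrt(tot_ss / length(x)) < tight_rms) k_range[1]
    else select_elbow(k_range, wss)
  i_best <- match(k_best, k_range)
  list(k = k_best, assignments = fits[[i_best]]$cluster, wss = wss,
       centers = fits[[i_best]]$centers, rows_used = rownames(x))
}
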