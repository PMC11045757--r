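#' Default 10-point dose grid
#'
#' Ten log-spaced concentrations from 1 nM to 10 uM (molar), the dose range
#' used in 10-point dose-response growth assays.
#'
#' @return Numeric vector of 10 strictly increasing molar concentrations.
#' @export
default_dose_grid <- function() {
  10^seq(log10(1e-9), log10(1e-5), length.out = 10)
}

#' Simulate a two-compound pooled viability screen
#'
#' Generates Hill-curve dose-response viability series for a panel of cell
#' lines treated with a bromodomain-targeting compound (`"BRDi"`) and a
#' HAT-domain-targeting compound (`"HATi"`), with planted
#' compound-preferential lines and multiplicative lognormal noise. Planted
#' `brd_preferential` lines have their BRDi IC50 divided by `ic50_shift`
#' (and symmetrically for `hat_preferential` lines), so the downstream
#' normalized AUC-ratio statistic can be validated against known truth.
#'
#' Defaults emulate the screened panel: 460 lines over 31 lineages with
#' 49 BRD-preferential and 63 HAT-preferential lines planted.
#'
#' @param n_lines Number of cell lines.
#' @param n_lineages Number of lineages lines are assigned to. Assignment
#'   is random with Zipf-weighted lineage probabilities, so a few lineages
#'   are rare -- as rare tumor types are in real panels -- and can fall
#'   under downstream minimum-size filters.
#' @param n_brd_preferential,n_hat_preferential Numbers of planted
#'   preferential lines; the remainder are neutral.
#' @param doses Strictly increasing positive molar dose grid.
#' @param ic50 Baseline IC50 (molar) for neutral line/compound pairs.
#' @param ic50_shift Fold-reduction in IC50 for the preferred compound of a
#'   planted line. The default (5) reproduces the mild preferential
#'   responses seen in real panels (normalized AUC ratios around 0.7-0.8
#'   and ratio-tail fractions near 13%/8%); recovery benchmarks use an
#'   explicit 100-fold shift.
#' @param ic50_jitter_sdlog10 Per line-compound lognormal jitter (in log10
#'   units) of the IC50 around its class value.
#' @param shared_sensitivity_sdlog10 Per-line IC50 offset (log10 units)
#'   shared by both compounds: intrinsically fragile or robust lines.
#'   Induces the weak positive between-compound AUC correlation seen in
#'   real panels; it largely cancels in the per-line AUC ratio.
#' @param slope Hill slope (> 0).
#' @param floor Viability floor at infinite dose, in [0, 1].
#' @param noise_sd Sigma of the multiplicative lognormal viability noise.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list with `viability`, a long data.frame with columns
#'   `cell_line`, `lineage`, `compound`, `dose_molar`, `viability`; and
#'   `truth`, a data.frame with `cell_line`, `class`
#'   (brd_preferential / hat_preferential / neutral).
#' @export
simulate_screen <- function(n_lines = 460, n_lineages = 31,
                            n_brd_preferential = 49,
                            n_hat_preferential = 63,
                            doses = default_dose_grid(),
                            ic50 = 1e-6, ic50_shift = 5,
                            ic50_jitter_sdlog10 = 0.25,
                            shared_sensitivity_sdlog10 = 0.2,
                            slope = 1.5, floor = 0.05,
                            noise_sd = 0.05, seed = 1L) {
  stopifnot(n_lines >= 1, n_lineages >= 1,
            n_brd_preferential + n_hat_preferential <= n_lines)
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (floor < 0 || floor > 1) stop("floor must be in [0, 1]")
  if (slope <= 0) stop("slope must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  set.seed(seed)
  lines <- sprintf("LINE%04d", seq_len(n_lines))
  lineages <- sprintf("lineage%02d",
                      sample(seq_len(n_lineages), n_lines, replace = TRUE,
                             prob = 1 / seq_len(n_lineages)))
  class <- rep("neutral", n_lines)
  planted <- sample.int(n_lines, n_brd_preferential + n_hat_preferential)
  class[planted[seq_len(n_brd_preferential)]] <- "brd_preferential"
  if (n_hat_preferential > 0)
    class[planted[n_brd_preferential + seq_len(n_hat_preferential)]] <-
      "hat_preferential"

  compounds <- c("BRDi", "HATi")
  shared <- rnorm(n_lines, 0, shared_sensitivity_sdlog10)
  rows <- vector("list", n_lines * 2L)
  k <- 0L
  for (i in seq_len(n_lines)) {
    for (cmp in compounds) {
      shift <- 1
      if (class[i] == "brd_preferential" && cmp == "BRDi") shift <- ic50_shift
      if (class[i] == "hat_preferential" && cmp == "HATi") shift <- ic50_shift
      ic <- (ic50 / shift) *
        10^(shared[i] + rnorm(1, 0, ic50_jitter_sdlog10))
      v <- floor + (1 - floor) / (1 + (doses / ic)^slope)
      v <- v * exp(rnorm(length(doses), 0, noise_sd))
      k <- k + 1L
      rows[[k]] <- data.frame(cell_line = lines[i], lineage = lineages[i],
                              compound = cmp, dose_molar = doses,
                              viability = v, stringsAsFactors = FALSE)
    }
  }
  list(viability = do.call(rbind, rows),
       truth = data.frame(cell_line = lines, lineage = lineages,
                          class = class, stringsAsFactors = FALSE))
}

#' Simulate a spike-in controlled RNA-seq count matrix
#'
#' Draws negative-binomial endogenous counts for a two-condition design
#' (control vs treated, `n_replicates` each) with an optional planted set of
#' differentially expressed genes and an optional condition-level global
#' multiplier applied to endogenous genes only. A panel of `n_spikeins`
#' synthetic spike-in rows (IDs `"ERCC-00001"` ...) has fixed true abundances
#' (log-uniform over 2^0..2^15) that are scaled only by per-sample technical
#' depth, never by the global shift -- mimicking external RNA controls added
#' per cell. This is the construction that lets spike-in-anchored size
#' factors see a global transcriptional collapse that library-size factors
#' normalize away.
#'
#' @param n_genes Number of endogenous genes.
#' @param n_spikeins Number of spike-in control rows (default 92).
#' @param n_replicates Replicates per condition (default 3).
#' @param baseline_meanlog,baseline_sdlog Lognormal (natural-log) parameters
#'   of endogenous baseline mean counts.
#' @param dispersion_a0,dispersion_a1 Dispersion trend alpha(mu) = a0 + a1/mu
#'   evaluated at each gene's baseline mean.
#' @param de_fraction Fraction of endogenous genes with planted differential
#'   expression.
#' @param de_lfc Either a single log2 fold change applied (with random sign
#'   if `de_random_sign`) to all planted genes, or a vector to sample from.
#' @param de_random_sign Randomize the sign of planted log2 fold changes.
#' @param global_shift Multiplier applied to endogenous means in the treated
#'   condition only (1 = none; 0.5 emulates a 2-fold global collapse).
#' @param depth_sdlog Lognormal sigma of per-sample technical depth.
#' @param spike_dispersion Technical NB dispersion of spike-in counts.
#' @param read_length Read length in bp, carried into the returned metadata
#'   for TPM computation (default 100).
#' @param seed Integer seed.
#'
#' @return List with `counts` (integer matrix, genes then spike-ins by
#'   samples), `sample_info` (data.frame: sample, condition), `lengths`
#'   (named vector of exon-union / reference lengths for all rows),
#'   `spikein_ids`, `read_length`, and `truth` (list: `lfc` named per-gene
#'   true log2 fold changes, `de_genes`, `depth`, `global_shift`,
#'   `spike_abundance`).
#' @export
simulate_counts <- function(n_genes = 2000, n_spikeins = 92,
                            n_replicates = 3,
                            baseline_meanlog = log(200),
                            baseline_sdlog = 1.2,
                            dispersion_a0 = 0.01, dispersion_a1 = 2,
                            de_fraction = 0.1, de_lfc = 2,
                            de_random_sign = TRUE,
                            global_shift = 1, depth_sdlog = 0.15,
                            spike_dispersion = 0.005,
                            read_length = 100, seed = 1L) {
  stopifnot(n_genes >= 1, n_spikeins >= 1, n_replicates >= 1,
            de_fraction >= 0, de_fraction <= 1, global_shift > 0,
            read_length > 0)
  set.seed(seed)

  genes <- sprintf("GENE%05d", seq_len(n_genes))
  spikes <- sprintf("ERCC-%05d", seq_len(n_spikeins))
  samples <- c(sprintf("control_%d", seq_len(n_replicates)),
               sprintf("treated_%d", seq_len(n_replicates)))
  condition <- rep(c("control", "treated"), each = n_replicates)

  base_mu <- exp(rnorm(n_genes, baseline_meanlog, baseline_sdlog))
  alpha <- dispersion_a0 + dispersion_a1 / base_mu

  lfc <- stats::setNames(numeric(n_genes), genes)
  n_de <- round(de_fraction * n_genes)
  de_genes <- character(0)
  if (n_de > 0) {
    idx <- sample.int(n_genes, n_de)
    de_genes <- genes[idx]
    mag <- if (length(de_lfc) == 1L) rep(de_lfc, n_de) else
      sample(de_lfc, n_de, replace = TRUE)
    sgn <- if (de_random_sign) sample(c(-1, 1), n_de, replace = TRUE) else 1
    lfc[idx] <- mag * sgn
  }

  depth <- stats::setNames(exp(rnorm(length(samples), 0, depth_sdlog)),
                           samples)
  # spike-in true abundances: fixed across conditions, log-uniform 2^0..2^15
  spike_ab <- stats::setNames(2^stats::runif(n_spikeins, 0, 15), spikes)

  counts <- matrix(0L, n_genes + n_spikeins, length(samples),
                   dimnames = list(c(genes, spikes), samples))
  for (s in seq_along(samples)) {
    shift <- if (condition[s] == "treated") global_shift else 1
    fc <- if (condition[s] == "treated") 2^lfc else rep(1, n_genes)
    mu_g <- base_mu * fc * shift * depth[s]
    counts[seq_len(n_genes), s] <-
      stats::rnbinom(n_genes, mu = mu_g, size = 1 / alpha)
    counts[n_genes + seq_len(n_spikeins), s] <-
      stats::rnbinom(n_spikeins, mu = spike_ab * depth[s],
                     size = 1 / spike_dispersion)
  }

  lengths <- c(stats::setNames(round(exp(rnorm(n_genes, log(1500), 0.6))),
                               genes),
               stats::setNames(round(stats::runif(n_spikeins, 250, 2000)),
                               spikes))

  list(counts = counts,
       sample_info = data.frame(sample = samples, condition = condition,
                                stringsAsFactors = FALSE),
       lengths = lengths, spikein_ids = spikes, read_length = read_length,
       truth = list(lfc = lfc, de_genes = de_genes, depth = depth,
                    global_shift = global_shift,
                    spike_abundance = spike_ab))
}

#' Simulate a Chronos-style gene-effect dependency matrix
#'
#' Gene-by-cell-line CRISPR gene-effect scores: planted dependency genes are
#' drawn around `dependency_mean` (strongly negative), all others around 0.
#' Default line names are the seven medulloblastoma lines of a 22Q4-style
#' dependency release.
#'
#' @param n_genes Number of genes.
#' @param lines Character vector of cell-line names (>= 1).
#' @param planted_genes Indices or names of planted dependency genes; if
#'   `NULL`, `n_planted` genes are sampled.
#' @param n_planted Number of planted genes when `planted_genes` is `NULL`.
#' @param dependency_mean Mean effect score of planted genes (default -1).
#' @param sd Score standard deviation (default 0.2).
#' @param seed Integer seed.
#'
#' @return List with `scores` (matrix genes x lines) and `truth`
#'   (character vector of planted dependency genes).
#' @export
simulate_dependency <- function(n_genes = 500,
                                lines = c("UW228", "DAOY", "ONS76", "D458",
                                          "D425", "D283MED", "D341MED"),
                                planted_genes = NULL, n_planted = 50,
                                dependency_mean = -1.0, sd = 0.2,
                                seed = 1L) {
  stopifnot(n_genes >= 1, length(lines) >= 1, sd > 0)
  set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  if (is.null(planted_genes)) {
    stopifnot(n_planted <= n_genes)
    planted <- genes[sample.int(n_genes, n_planted)]
  } else {
    planted <- if (is.numeric(planted_genes)) genes[planted_genes]
      else planted_genes
    if (!all(planted %in% genes)) stop("planted genes outside gene universe")
  }
  mu <- ifelse(genes %in% planted, dependency_mean, 0)
  scores <- matrix(stats::rnorm(n_genes * length(lines), mean = mu, sd = sd),
                   n_genes, length(lines),
                   dimnames = list(genes, lines))
  list(scores = scores, truth = sort(planted))
}

#' Simulate an interaction graph with a planted dense module
#'
#' Confidence-weighted undirected edge list over a gene vocabulary, with a
#' planted module wired at high edge probability against a sparse
#' background; edge confidences are uniform on [0.4, 1], mirroring
#' medium-confidence interaction databases.
#'
#' @param genes Character vector of node names.
#' @param module_genes Subset of `genes` forming the planted module.
#' @param p_within Edge probability inside the module (default 0.8).
#' @param p_background Edge probability elsewhere (default 0.02).
#' @param conf_range Range of uniform edge confidences.
#' @param seed Integer seed.
#'
#' @return data.frame with columns `gene_a`, `gene_b`, `confidence`.
#' @export
simulate_graph <- function(genes, module_genes, p_within = 0.8,
                           p_background = 0.02, conf_range = c(0.4, 1),
                           seed = 1L) {
  stopifnot(length(genes) >= 2, all(module_genes %in% genes))
  set.seed(seed)
  pairs <- utils::combn(genes, 2)
  in_mod <- pairs[1, ] %in% module_genes & pairs[2, ] %in% module_genes
  p <- ifelse(in_mod, p_within, p_background)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
             confidence = stats::runif(sum(keep), conf_range[1],
                                       conf_range[2]),
             stringsAsFactors = FALSE)
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Random A/C/G/T sequences in which a consensus motif (default the E-box
#' CACGTG) is planted with per-promoter probability `motif_rate` at a random
#' position. Chance occurrences of the motif in the random background remain,
#' as in real promoters.
#'
#' @param n Number of promoters.
#' @param width Promoter length in bp (default 500).
#' @param motif Motif string planted (default "CACGTG").
#' @param motif_rate Probability that a promoter receives a planted site.
#' @param prefix Name prefix for the returned records.
#' @param seed Integer seed.
#'
#' @return Named character vector of promoter sequences.
#' @export
simulate_promoters <- function(n, width = 500, motif = "CACGTG",
                               motif_rate = 0.1, prefix = "prom",
                               seed = 1L) {
  stopifnot(n >= 1, width > nchar(motif), motif_rate >= 0, motif_rate <= 1)
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    if (stats::runif(1) < motif_rate) {
      pos <- sample.int(width - nchar(motif) + 1L, 1)
      s[pos:(pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    }
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- sprintf("%s%04d", prefix, seq_len(n))
  out
}
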