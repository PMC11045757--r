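---
title: "Comparing domain-specific inhibitors: screen analytics, spike-in anchored differential expression, and dependency integration"
author: "domainsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing domain-specific inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainsens)
```

# The scientific problem

Multidomain chromatin regulators such as the paralogous acetyltransferases
EP300 and CBP can be drugged at more than one domain: the catalytic HAT
domain (e.g. by A485) or the acetyl-lysine-binding bromodomain (e.g. by
CCS1477). The two modes of inhibition are not equivalent, and some tumor
types — notably MYC-amplified Group 3 medulloblastoma — respond far more
strongly to bromodomain inhibition. Establishing that requires a chain of
analyses, each with its own statistical pitfalls:

1. **Screen analytics.** Pooled viability screens summarize each cell line
   by an area under the dose-response curve (AUC); comparing two compounds
   screened non-simultaneously requires per-compound median normalization,
   and per-line preference is read off the normalized AUC ratio.
2. **Spike-in anchored transcriptomics.** Drugs that hit general
   transcriptional machinery shift *total* mRNA per cell. Any
   normalization that equalizes library composition (TPM alone, library
   size factors) silently erases such a global shift. External RNA
   controls (ERCC spike-ins) added per cell provide an anchor that
   preserves it.
3. **Dependency integration.** Whether drug-downregulated genes matter for
   growth is asked by intersecting them with CRISPR gene-effect screens
   and testing overlap differences between compounds exactly.

`domainsens` implements this chain with a seed-deterministic simulator for
every input, so each stage is testable against known ground truth.

# Screen analytics

## AUC definition

A viability series (10 doses, fraction-of-control viability) is summarized
by the trapezoidal integral of viability over `log10(dose)`, divided by the
log10-dose range:

$$\mathrm{AUC} = \frac{1}{x_{10}-x_1}\int_{x_1}^{x_{10}} v(x)\,dx,
\qquad x = \log_{10}(\text{dose}).$$

A fully unaffected line scores exactly 1, a fully killed line 0. This
definition is parameter-free and monotone: pointwise-lower viability never
yields a higher AUC. Viability is clipped to `[0, 1.2]` first (`cap`,
configurable) to bound growth-stimulation artifacts. A four-parameter
logistic alternative (`method = "4pl"`) integrates a fitted Hill curve
instead; the trapezoid is the tested default because it makes no
convergence demands on noisy series.

## Normalization and the ratio statistic

AUCs are divided by their per-compound median (`median_normalize`), making
the normalized median exactly 1 and per-line ratios invariant to any global
rescaling of either compound's assay. The per-line statistic is

$$r = \frac{\mathrm{normAUC}_{\mathrm{BRDi}}}{\mathrm{normAUC}_{\mathrm{HATi}}},$$

classified with strict thresholds: $r > 1.2$ means the HAT inhibitor was
relatively more effective (`hat_preferential`), $r < 0.8$ the bromodomain
inhibitor (`brd_preferential`); a ratio exactly at a threshold is neutral.
Lineage summaries report the per-lineage median ratio and drop lineages
with fewer than 3 lines; dropped lines are not counted in the retained
total.

An open question we had to decide: whether a small validation panel should
be normalized against itself or against a full-screen reference. The
functions normalize within whatever table they are given; this is the
documented behavior, and ratios are unaffected by the choice whenever both
compounds are normalized consistently.

## What the screen simulator emulates

`simulate_screen` draws Hill-curve viabilities
$v(d) = \mathrm{floor} + (1-\mathrm{floor})/(1+(d/\mathrm{IC50})^{s})$
with multiplicative lognormal noise (screen readouts are positive and
heteroskedastic). Defaults mirror the screened panel: 460 lines, 31
lineages, 49 planted BRD-preferential and 63 HAT-preferential lines, a
10-point log-spaced 1 nM–10 µM dose grid. Lineage assignment is
Zipf-weighted so rare tumor types exist and can fall under the minimum-size
filter. Each line carries a shared sensitivity component
(`shared_sensitivity_sdlog10 = 0.2`) affecting both compounds — this
reproduces the weak positive between-compound AUC correlation of real
panels and largely cancels in the ratio. The default planted IC50 shift is
5-fold, which yields mild preferential ratios (~0.75) and ratio-tail
fractions near 12%/8%, in the range reported for real panels; recovery
benchmarks use an explicit 100-fold shift, under which the ratio classifier
recovers essentially all planted lines. Screen noise magnitude is not a
published quantity; `noise_sd = 0.05` was chosen once for test power, not
realism.

# TPM and spike-in anchored loess

## Exon-union lengths and TPM

Gene length is the union of all exon intervals across all isoforms
(overlaps merged, duplicates ignored; GTF coordinates are 1-based
inclusive; strand is irrelevant to length). TPM uses the explicit
read-length form

$$\mathrm{rate}_g = \frac{c_g \cdot L_r}{\ell_g},\qquad
\mathrm{TPM}_g = \frac{\mathrm{rate}_g}{\sum_h \mathrm{rate}_h}\times 10^6,$$

with spike-in rows included in the denominator. The read length $L_r$
(default 100 bp, paired-end sequencing convention) cancels within a sample
but is retained for fidelity to the standard formula. Column sums are
exactly $10^6$.

## MA-loess on spike-ins only

TPM equalizes composition within samples; between samples, an
intensity-dependent bias remains, and — crucially — a genuine global shift
of endogenous transcription is *invisible* to any endogenous-only
normalization. `loess_normalize` therefore fits, per sample, a loess curve
of $M = \log_2(\mathrm{sample}) - \log_2(\mathrm{reference})$ on
$A = \tfrac12(\log_2(\mathrm{sample}) + \log_2(\mathrm{reference}))$
**using spike-in rows only**, and subtracts the fitted curve from all rows.
The reference is the per-row mean of log2 TPM across samples (a
geometric-mean pseudo-reference), so output does not depend on sample
ordering.

Numerical choices, made once and documented here because no published
parameterization exists for this step:

* span 0.5, local degree 2, `family = "symmetric"` with 4 robustifying
  iterations;
* pseudocount 0.5 added before the log and removed after
  back-transformation (values clipped at 0);
* constant extension of the fitted curve beyond the spike-in A-range —
  extrapolating a local polynomial is the classic failure mode;
* a sample whose spike-in M is exactly constant (identical or perfectly
  scaled samples) is corrected by subtracting that constant, since a
  robust loess is undefined at zero residual spread;
* at least 8 spike-ins positive in every sample are required.

Two properties matter scientifically and are tested: a planted global
shift applied to a whole sample is removed (the *median* spike-in
log-ratio returns to ~0), while a shift applied to endogenous rows only is
*retained* (~2-fold after normalization). We summarize the systematic
residual by the median across spike-ins rather than the mean of absolute
values: low-abundance spike-ins carry irreducible counting noise (per-spike
|M| of order 0.2 even between technical replicates), which no normalization
can remove and which would swamp a mean of absolute residuals. For the same
reason the normalization is only approximately idempotent: a second
application re-smooths spike counting noise, changing the bulk of values by
under 0.05 log2 units (median ~0.01) with boundary effects bounded by ~0.5;
exact idempotency would require noiseless controls.

# Control-gene differential expression

The engine approximates — deliberately does not reproduce — the
DESeq2-with-controlGenes analysis. The test surface is agreement with
generative truth on simulations, not numeric identity with another
implementation (which is instead used as an independent concordance check
in the test suite).

* **Size factors**: median-of-ratios computed on spike-in rows only;
  control rows with any zero are excluded (the geometric-mean reference is
  undefined at zero); factors are rescaled to geometric mean 1. Library
  size (total-count) factors are provided for contrast.
* **Dispersions**: per-gene method-of-moments
  $\hat\alpha = \max(\mathrm{floor}, (s^2-\bar\mu)/\bar\mu^2)$ on
  normalized counts, pooling within-condition variance so real effects do
  not inflate dispersion; a trend $\alpha(\mu) = a_0 + a_1/\mu$ fit over
  genes with $\bar\mu \ge 5$ and an informative gene-wise estimate (one
  outlier-trimmed refit); final dispersion blends trend and gene-wise
  estimates on the log scale with weight 0.5. Genes whose moment estimate
  collapses to the floor carry no usable gene-wise signal and take the
  trend value — blending from the floor itself would hand them a
  near-Poisson dispersion and visibly inflate false positives.
* **Wald tests**: per-gene NB GLM (log link, intercept + condition, log
  size-factor offsets, fixed dispersion); log2 fold change is the
  condition coefficient over $\log 2$. Two-sided p-values use a **t
  reference with $n-2$ degrees of freedom**: at 3 vs 3 replicates the Wald
  ratio is distinctly heavier-tailed than normal because the standard
  error is itself estimated from six observations — with a normal
  reference the empirical type-I error at nominal 0.05 is about 0.11,
  with the t reference 0.04–0.05 (and the two references coincide as
  replication grows). All-zero genes get `NA` and are excluded from the
  Benjamini–Hochberg denominator.
* **High-confidence sets**: a gene is high-confidence down for a treatment
  if `padj < 0.05` with negative log2 fold change in *every* cell line
  analyzed (symmetrically for up); genes significant everywhere but
  discordant in direction are excluded. We read "union of high-confidence
  up- or downregulated genes" as this per-direction intersection across
  lines, then the union of the up- and down-labeled results.

## Why anchor on spike-ins

The decisive scenario, simulated in the tests and the acceptance script: a
treatment halves endogenous transcription per cell with no gene-specific
effects. With spike-anchored size factors the pipeline calls the genuine
~2-fold downregulation across endogenous genes with almost no false calls
on the (truly unchanged) spike-ins. With library-size factors the global
shift is absorbed into the normalization: the endogenous change vanishes
from the results and the unchanged spike-ins surface as strongly
"upregulated" false positives — in our simulations more than half of all
significant calls. This is precisely the failure mode external controls
exist to prevent.

## What the count simulator does and does not emulate

`simulate_counts` draws NB endogenous counts (lognormal baseline means,
dispersion trend $\alpha(\mu) = 0.01 + 2/\mu$, values typical of cell-line
triplicates), planted log2 fold changes, a condition-level global
multiplier on endogenous genes only, and 92 spike-in rows with fixed
log-uniform abundances over $2^0..2^{15}$ (synthetic IDs, mimicking the
structure of a commercial mix without redistributing vendor data) scaled
only by per-sample technical depth. It does not emulate read-level
artifacts (GC bias, positional coverage, mapping ambiguity), batch
structure, or outlier samples — so passing tests demonstrate statistical
correctness of the engine under its stated model, not robustness to every
real-data pathology.

# Dependency and network integration

Dependencies are genes with a Chronos-style gene-effect score strictly
below −0.5 in at least 3 of the panel's (default seven) cell lines — the
"more than 2 of 7" rule. Overlaps between drug-downregulated sets and the
dependency set are compared with a two-sided Fisher exact test implemented
by direct enumeration of the hypergeometric support with the
probability-ordering rule (tables as or less probable than the observed
one, compared within relative tolerance $10^{-7}$ to avoid floating-point
ties). The implementation is checked exhaustively against an independent
reference for every 2×2 table with total at most 30.

Network context comes from a confidence-weighted undirected edge list
(medium confidence = 0.4 cutoff by default), decoupled from any remote
interaction database. `subgraph_stats` reports induced edge count, mean
degree, connected fraction, largest-component fraction, and a permutation
z-score of the edge count against size-matched random gene sets
(seeded; degree-matched nulls are a possible extension, not implemented).

# Clustering and enrichment

* `kmeans_elbow` runs k-means for each candidate k (best of 20 seeded
  random restarts plus a warm start that splits the previous solution's
  worst-fit point, which guarantees a non-increasing WSS curve) and picks
  k by the maximum-chord-distance ("kneedle") formalization of the elbow
  rule. Degenerate inputs: a WSS curve with range below $10^{-9}$, or
  data whose RMS spread around the grand centroid is below 0.01 (one
  tight cluster), return the smallest k. Rows are standardized by default,
  the fold-change-heatmap convention.
* `hypergeometric_enrichment` is the exact upper-tail test
  $P(X \ge k)$ — identical to the one-sided Fisher tail of the
  corresponding 2×2 — with BH adjustment across sets; it stands in for
  remote over-representation services on user-supplied GMT collections.
* `motif_scan` counts sliding-window matches to an IUPAC consensus
  (default the E-box CACGTG, the canonical MYC/MAX site). With
  both-strand scanning, a window matching on both strands is counted
  once — for a palindrome like CACGTG the two strands are the same site.
  Promoter window choice and background set are caller inputs; the motif
  analysis is a stand-in for unnamed published tooling, not a
  reproduction. Enrichment dichotomizes promoters as motif-positive and
  uses the same exact Fisher machinery as the dependency module.

# Problem sizes and determinism

All simulators are bitwise seed-deterministic. The test suite and the
acceptance script use moderate problem sizes chosen to keep Monte-Carlo
error well inside the asserted margins: 2,000-gene count matrices with 3
vs 3 replicates for DE calibration and power, 1,500 genes for
normalization checks, 500-gene dependency matrices, 300-node graphs with
200 permutations, 240 rows for clustering, and 100 query vs 1,000
background promoters. `scripts/acceptance.R --seed <s> --out <path>`
recomputes every headline quantity from scratch at these sizes.

# Known limitations

* The DE engine omits DESeq2's MAP dispersion estimator, Cook's-distance
  outlier handling, independent filtering and LFC shrinkage; it
  approximates the analysis, with simulation truth as the accuracy
  criterion.
* Fold-change standard errors come from the observed information of a
  plug-in-dispersion GLM; uncertainty in the dispersion enters only
  through the t reference's degrees of freedom.
* The loess anchor assumes at least 8 informative spike-ins per sample and
  inherits the usual MA-normalization assumption that controls span the
  intensity range of interest.
* Permutation nulls for subgraph connectivity are size-matched but not
  degree-matched.
* Barcode deconvolution, read alignment/counting, GSEA running-sum
  statistics, and remote annotation services are out of scope; their
  outputs are inputs here.
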