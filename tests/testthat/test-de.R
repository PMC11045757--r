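test_that("control-gene size factors: identity, scaling, zero handling", {
  ctrl <- paste0("ERCC-", 1:10)
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(ctrl, paste0("s", 1:4)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(control_gene_size_factors(same, ctrl)), rep(1, 3))

  # sample B doubled on every control row: factors 1/sqrt(2), sqrt(2)
  two <- cbind(A = m[, 1], B = 2 * m[, 1])
  f <- control_gene_size_factors(two, ctrl)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))

  # scale equivariance before the geometric-mean rescaling: scaling one
  # sample by c scales its factor by c relative to the others
  sc <- m; sc[, 2] <- sc[, 2] * 3
  f0 <- control_gene_size_factors(m, ctrl)
  f1 <- control_gene_size_factors(sc, ctrl)
  expect_equal(f1[2] / f1[1], 3 * f0[2] / f0[1], tolerance = 1e-12)

  # control rows with a zero anywhere are excluded from the reference
  z <- m; z[1, 1] <- 0
  keep <- control_gene_size_factors(z, ctrl)
  manual <- control_gene_size_factors(z[-1, ], ctrl[-1])
  expect_equal(keep, manual)
  allzero <- matrix(0, 2, 2, dimnames = list(ctrl[1:2], c("a", "b")))
  expect_error(suppressWarnings(control_gene_size_factors(allzero, ctrl)),
               "no control rows")
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  set.seed(20)
  n <- 20
  pois <- matrix(rpois(500 * n, 100), 500, n,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:n)))
  d <- estimate_dispersions(pois, rep(1, n))
  expect_lt(median(d$alpha), 0.05)

  nb <- matrix(rnbinom(500 * n, mu = 100, size = 1 / 0.2), 500, n,
               dimnames = dimnames(pois))
  d2 <- estimate_dispersions(nb, rep(1, n))
  expect_gt(median(d2$alpha_mom), 0.1)
  expect_lt(median(d2$alpha_mom), 0.3)

  cst <- matrix(50, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  d3 <- estimate_dispersions(cst, rep(1, 4))
  expect_equal(unname(d3$alpha_mom), rep(1e-8, 5))
  expect_error(estimate_dispersions(pois[, 1, drop = FALSE], 1), "2 samples")
  expect_error(estimate_dispersions(pois[, 1:3], rep(1, 3),
                                    condition = c("a", "a", "b")),
               "at least 2 samples")
})

test_that("Wald test sign convention and degenerate genes", {
  sim <- simulate_counts(n_genes = 150, de_fraction = 0.2, de_lfc = 2,
                         seed = 21)
  res <- run_de_pipeline(sim)
  up <- names(sim$truth$lfc)[sim$truth$lfc > 0]
  strong <- res$gene_id %in% up & res$base_mean > 50
  expect_true(all(res$log2fc[strong] > 0))
  # padj >= p wherever both are defined
  ok <- !is.na(res$padj)
  expect_true(all(res$padj[ok] >= res$p[ok] - 1e-12))
  # all-zero gene: NA p, excluded from adjustment
  counts <- sim$counts
  counts["GENE00001", ] <- 0
  sf <- control_gene_size_factors(counts, sim$spikein_ids)
  cond <- sim$sample_info$condition
  endo <- setdiff(rownames(counts), sim$spikein_ids)
  disp <- estimate_dispersions(counts[endo, ], sf, condition = cond)
  r2 <- wald_test(counts[endo, ], sf, disp$alpha,
                  treated = sim$sample_info$sample[cond == "treated"],
                  control = sim$sample_info$sample[cond == "control"])
  expect_true(is.na(r2$p[r2$gene_id == "GENE00001"]))
  expect_identical(r2$direction[r2$gene_id == "GENE00001"], "ns")
})

test_that("Benjamini-Hochberg adjustment: step-up, NA handling, monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  # NAs excluded from the number of tests
  expect_equal(bh_adjust(c(0.01, NA, 0.02)), c(0.02, NA, 0.02))
  set.seed(22)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.5)), "outside")
})

test_that("high-confidence sets require concordant significance in all lines", {
  mk <- function(padj, lfc)
    data.frame(gene_id = paste0("g", seq_along(padj)), base_mean = 100,
               log2fc = lfc, se = 1, wald = lfc, p = padj, padj = padj,
               direction = "ns", stringsAsFactors = FALSE)
  a <- mk(c(0.01, 0.01, 0.01, 0.5, 0.01), c(-2, 2, -2, -2, -2))
  b <- mk(c(0.02, 0.02, 0.6, 0.01, 0.01), c(-1, 1, -1, -1, 2))
  hc <- high_confidence_sets(list(lineA = a, lineB = b))
  expect_identical(hc$down, "g1")   # concordant down in both
  expect_identical(hc$up, "g2")
  # g3 significant in one line only; g5 significant but discordant
  expect_false("g3" %in% c(hc$up, hc$down))
  expect_false("g5" %in% c(hc$up, hc$down))
  expect_error(high_confidence_sets(list(a)), ">= 2")
  expect_warning(high_confidence_sets(list(a, b[-5, ])), "intersecting")
})

test_that("permuted labels give uniform tail p-values", {
  sim <- simulate_counts(n_genes = 800, de_fraction = 0.15, de_lfc = 2,
                         seed = 23)
  # permutation that mixes conditions: 2 treated + 1 control vs rest
  sf <- control_gene_size_factors(sim$counts, sim$spikein_ids)
  endo <- setdiff(rownames(sim$counts), sim$spikein_ids)
  perm_t <- c("treated_1", "control_2", "treated_3")
  perm_c <- c("control_1", "treated_2", "control_3")
  disp <- estimate_dispersions(
    sim$counts[endo, ], sf,
    condition = ifelse(colnames(sim$counts) %in% perm_t, "a", "b"))
  res <- wald_test(sim$counts[endo, ], sf, disp$alpha, perm_t, perm_c)
  p <- res$p[!is.na(res$p)]
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.05)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.07)
})

test_that("significance calls agree with DESeq2 on a strong-effect simulation", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(n_genes = 400, de_fraction = 0.1, de_lfc = 3,
                         seed = 24)
  res <- run_de_pipeline(sim)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts, S4Vectors::DataFrame(condition = factor(
        sim$sample_info$condition, c("control", "treated"))),
      ~condition)
    dds <- DESeq2::estimateSizeFactors(
      dds, controlGenes = rownames(sim$counts) %in% sim$spikein_ids)
    dds <- suppressWarnings(DESeq2::DESeq(dds, quiet = TRUE))
    dr <- DESeq2::results(dds)
  })
  endo <- setdiff(rownames(sim$counts), sim$spikein_ids)
  shared <- intersect(endo, rownames(dr)[!is.na(dr$padj)])
  mine <- res$padj[match(shared, res$gene_id)] < 0.05
  theirs <- dr[shared, "padj"] < 0.05
  strong <- res$base_mean[match(shared, res$gene_id)] > 50
  agree <- mean(mine[strong] == theirs[strong], na.rm = TRUE)
  expect_gt(agree, 0.9)
  # fold-change estimates track each other
  expect_gt(cor(res$log2fc[match(shared, res$gene_id)],
                dr[shared, "log2FoldChange"]), 0.95)
})
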