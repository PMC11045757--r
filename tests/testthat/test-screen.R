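test_that("AUC of flat, killed and log-linear viability curves", {
  d <- default_dose_grid()
  expect_identical(compute_auc(d, rep(1, 10)), 1)
  expect_identical(compute_auc(d, rep(0, 10)), 0)
  # viability linear in log-dose from 1 to 0
  v <- seq(1, 0, length.out = 10)
  expect_equal(compute_auc(d, v), 0.5)
  # clipping: growth stimulation capped at 1.2
  expect_equal(compute_auc(d, rep(5, 10)), 1.2)
  expect_error(compute_auc(d[1], 1), "at least 2")
  expect_error(compute_auc(d, c(rep(1, 9), NA)), "non-finite")
  expect_error(compute_auc(rev(d), rep(1, 10)), "increasing")
})

test_that("AUC is monotone: pointwise-lower viability never scores higher", {
  set.seed(10)
  d <- default_dose_grid()
  for (i in 1:25) {
    v <- runif(10, 0, 1.2)
    lower <- pmax(v - runif(10, 0, 0.3), 0)
    expect_lte(compute_auc(d, lower), compute_auc(d, v))
  }
})

test_that("4PL AUC agrees with the trapezoid on a clean Hill curve", {
  d <- default_dose_grid()
  v <- 0.05 + 0.95 / (1 + (d / 1e-7)^1.5)
  expect_lt(abs(compute_auc(d, v, method = "4pl") - compute_auc(d, v)),
            0.02)
})

test_that("median normalization fixes the median at 1", {
  expect_equal(median_normalize(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(median_normalize(c(3, 3, 3)), c(1, 1, 1))
  # even count: median is the mean of the two central order statistics
  expect_equal(median_normalize(c(1, 2, 3, 4)), c(0.4, 0.8, 1.2, 1.6))
  expect_error(median_normalize(c(NA_real_, NA_real_)), "finite")
  expect_error(median_normalize(c(-1, 0, 1)), "median is zero")
})

test_that("ratio table matches lines, drops strays and flags zero AUCs", {
  b <- c(A = 1, B = 0.5, C = 2)
  h <- c(A = 1, B = 1, D = 1)
  expect_warning(rt <- compute_ratio_table(b, h), "one compound")
  expect_setequal(rt$cell_line, c("A", "B"))
  expect_equal(rt$ratio[rt$cell_line == "A"], 1)
  expect_equal(rt$class[rt$cell_line == "B"], "brd_preferential")

  expect_warning(expect_warning(
    z <- compute_ratio_table(c(A = 1, B = 1), c(A = 0, B = 1, X = 2)),
    "one compound"), "zero HAT")
  expect_identical(z$cell_line, "B")
})

test_that("ratios are invariant to a global rescaling of one compound's AUCs", {
  set.seed(3)
  raw_b <- setNames(runif(11, 0.2, 1.2), paste0("L", 1:11))
  raw_h <- setNames(runif(11, 0.2, 1.2), paste0("L", 1:11))
  r1 <- compute_ratio_table(median_normalize(raw_b), median_normalize(raw_h))
  r2 <- compute_ratio_table(median_normalize(raw_b),
                            median_normalize(raw_h * 2))
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("ratio classification uses strict thresholds", {
  expect_identical(classify_ratio(c(0.68, 1.43, 1.0)),
                   c("brd_preferential", "hat_preferential", "neutral"))
  expect_identical(classify_ratio(1.2), "neutral")
  expect_identical(classify_ratio(0.8), "neutral")
  expect_identical(classify_ratio(1.2 + 1e-9), "hat_preferential")
  expect_error(classify_ratio(-1), "> 0")
})

test_that("lineage summaries exclude small lineages from the retained total", {
  ratios <- data.frame(cell_line = paste0("L", 1:8),
                       ratio = c(1, 1.1, 0.9, 1.4, 1.5, 1.3, 0.7, 0.6))
  map <- setNames(c(rep("lungs", 3), rep("brain", 3), rep("blood", 2)),
                  paste0("L", 1:8))
  out <- summarize_lineages(ratios, map, min_n = 3)
  expect_equal(nrow(out$summary), 2)
  expect_equal(out$n_retained_lines, 6)
  expect_false("blood" %in% out$summary$lineage)
  expect_equal(out$summary$median_ratio[out$summary$lineage == "brain"], 1.4)
  expect_error(summarize_lineages(ratios, map[-1]), "unmapped")
})

test_that("squared Pearson correlation on AUC vectors", {
  expect_equal(pairwise_r2(1:5, 1:5), 1)
  # hand calculation: r = 3 / sqrt(5 * 5) = 0.6
  expect_equal(pairwise_r2(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.36)
  # invariant to median normalization of either argument
  set.seed(4)
  x <- runif(20, 0.1, 1); y <- runif(20, 0.1, 1)
  expect_equal(pairwise_r2(x, y),
               pairwise_r2(median_normalize(x), median_normalize(y)))
  expect_error(pairwise_r2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pairwise_r2(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(pairwise_r2(c(1, NA, 3), c(1, 2, 3)), "paired finite")
})

test_that("screen classification recovers planted class proportions", {
  sim <- simulate_screen(n_lines = 120, n_lineages = 6,
                         n_brd_preferential = 24, n_hat_preferential = 24,
                         ic50_shift = 100, seed = 12)
  rt <- screen_ratio_table(sim)
  tab <- table(factor(rt$class, c("brd_preferential", "hat_preferential",
                                  "neutral")))
  # planted proportions 0.2 / 0.2 / 0.6, binomial error at n = 120
  expect_lt(abs(tab[["brd_preferential"]] / 120 - 0.2), 0.1)
  expect_lt(abs(tab[["hat_preferential"]] / 120 - 0.2), 0.1)
  expect_lt(abs(tab[["neutral"]] / 120 - 0.6), 0.12)
})

test_that("screen round-trips through the TSV reader", {
  sim <- simulate_screen(n_lines = 6, n_lineages = 2,
                         n_brd_preferential = 1, n_hat_preferential = 1,
                         seed = 13)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$viability, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_screen_tsv(f)
  expect_equal(back$viability, sim$viability$viability, tolerance = 1e-12)
  a1 <- compute_auc_table(sim$viability)
  a2 <- compute_auc_table(back)
  expect_equal(a1$raw_auc, a2$raw_auc, tolerance = 1e-10)
})
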