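# Shared fixtures: run the spike-in anchored DE pipeline on a simulation.
run_de_pipeline <- function(sim, size_factors = c("spike", "library"),
                            endogenous_only = TRUE, alpha = 0.05) {
  size_factors <- match.arg(size_factors)
  sf <- if (size_factors == "spike")
    control_gene_size_factors(sim$counts, sim$spikein_ids)
  else library_size_factors(sim$counts)
  rows <- if (endogenous_only)
    setdiff(rownames(sim$counts), sim$spikein_ids)
  else rownames(sim$counts)
  cond <- sim$sample_info$condition
  disp <- estimate_dispersions(sim$counts[rows, , drop = FALSE], sf,
                               condition = cond)
  wald_test(sim$counts[rows, , drop = FALSE], sf, disp$alpha,
            treated = sim$sample_info$sample[cond == "treated"],
            control = sim$sample_info$sample[cond == "control"],
            alpha = alpha)
}

# Per-compound normalized AUC vectors and the ratio table for a simulated
# screen.
screen_ratio_table <- function(sim, ...) {
  auc <- compute_auc_table(sim$viability)
  nb <- setNames(auc$norm_auc[auc$compound == "BRDi"],
                 auc$cell_line[auc$compound == "BRDi"])
  nh <- setNames(auc$norm_auc[auc$compound == "HATi"],
                 auc$cell_line[auc$compound == "HATi"])
  compute_ratio_table(nb, nh, ...)
}
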