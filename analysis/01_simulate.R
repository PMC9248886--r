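#!/usr/bin/env Rscript
# Stage 1: generate the synthetic longitudinal study.
#
# Emits every input the downstream stages consume, in the same plain-text
# formats a real study would arrive in: per-ome abundance matrices with
# shared collection windows, a metabolite reaction network with monoisotopic
# masses, the measured m/z feature list, an adduct table, and the clinical
# outcome panel.

suppressMessages(library(exponet))

out_dir <- "results/sim"
spec <- simulation_spec(seed = 1)
paths <- write_simulated_study(spec, out_dir)

sim <- simulate_blocks(spec)
cat("simulated", length(sim$blocks), "omic blocks over",
    spec$n_timepoints, "collection windows starting",
    as.character(spec$start_date), "\n")
for (o in names(sim$blocks)) {
  cat(sprintf("  %-14s %3d features\n", o, nrow(sim$blocks[[o]]$values)))
}
cat("planted cross-ome pairs:", nrow(sim$truth$planted_pairs),
    "at |rho| =", unique(sim$truth$planted_pairs$rho), "\n")
met <- simulate_metabolic_study(spec)
cat("metabolic network:", igraph::vcount(met$network$graph), "metabolites,",
    met$network$m, "reactions; planted module:",
    length(met$module_members), "members\n")
cat("wrote", length(paths), "files under", out_dir, "\n")
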