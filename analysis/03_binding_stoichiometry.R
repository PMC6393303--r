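#!/usr/bin/env Rscript
# Equilibrium titration analysis: simulate tight-binding anisotropy and
# intensity titrations of labelled template/primer with polymerase and read
# the binding stoichiometry off segmented fits, at two DNA concentrations.

library(clampkin)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

dir.create("results", showWarnings = FALSE)
cond <- study_conditions("titration")

rows <- lapply(c(50, 100), function(dna) {
  truth <- cond$truth
  truth$dna_total <- dna
  cfg <- generator_config("titration", truth, cond$grid, cond$sigma,
                          replicates = 1, seed = seed + dna)
  curve <- make_titration(cfg)
  write_titration(curve, sprintf("results/03_titration_%dnM.csv", dna))
  sf_int <- segmented_fit(curve, 2, signal = "intensity", dna_total = dna)
  sf_ani <- segmented_fit(curve, 2, signal = "anisotropy", dna_total = dna)
  data.frame(dna_nM = dna,
             breakpoint_intensity_nM = max(sf_int$breakpoints),
             stoichiometry_intensity = sf_int$stoichiometry,
             stoichiometry_anisotropy = sf_ani$stoichiometry)
})
tab <- do.call(rbind, rows)
cat("segmented-fit stoichiometry (intensity channel is the linear readout;\n")
cat("quenching bows the intensity-weighted anisotropy slightly high):\n")
print(tab, row.names = FALSE)
utils::write.csv(tab, "results/03_stoichiometry.csv", row.names = FALSE)

# recovery over replicates at the standard 50 nM condition
cfg <- generator_config("titration", cond$truth, cond$grid, cond$sigma,
                        replicates = 20, seed = seed)
rec <- recover_parameters(cfg)
cat("\nstoichiometry recovery over 20 replicates:\n"); print(rec)
utils::write.csv(as.data.frame(rec), "results/03_stoichiometry_recovery.csv",
                 row.names = FALSE)
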