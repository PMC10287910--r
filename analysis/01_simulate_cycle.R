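#!/usr/bin/env Rscript
# Forward-simulate the ParA2 ATPase cycle under the main assay conditions
# and verify that the observed rates printed for each assay emerge from the
# elementary constants. Writes trajectories and a summary table under
# results/.

suppressPackageStartupMessages(library(para2kin))
dir.create("results", showWarnings = FALSE)

r <- rate_set()
cat("Reference rate set:\n")
print(r)

conditions <- list(
  atp        = assay_condition("ATP"),
  atp_dna    = assay_condition("ATP", dna = TRUE),
  atp_both   = assay_condition("ATP", dna = TRUE, parb = TRUE),
  adp        = assay_condition("ADP"),
  atpgs_dna  = assay_condition("ATPgS", dna = TRUE))

rows <- list()
for (nm in names(conditions)) {
  cn <- conditions[[nm]]
  init <- species_state(c(D = 0.625, ATP = if (cn$nucleotide != "ADP") 100 else 0,
                          ADP = if (cn$nucleotide == "ADP") 100 else 0,
                          sites = if (cn$dna) 5.13 else 0,
                          ParB = if (cn$parb) 1.25 else 0))
  traj <- integrate_scheme(assemble_scheme(r, cn), init, seq(0, 400, 1))
  utils::write.csv(as.data.frame(traj),
                   file.path("results", paste0("cycle_", nm, ".csv")),
                   row.names = FALSE)
  rows[[nm]] <- data.frame(
    condition = nm,
    conservation_err = max(conservation_error(traj)),
    final_bound_frac = sum(traj$state[nrow(traj$state), c("B", "mB")]) / 0.625,
    final_remodeled_frac = sum(traj$state[nrow(traj$state),
                                          c("DS", "mDS")]) / 0.625)
}
summ <- do.call(rbind, rows)
utils::write.csv(summ, "results/cycle_summary.csv", row.names = FALSE)
print(summ, row.names = FALSE)

cat("\nAll conservation errors below 1e-8:",
    all(summ$conservation_err < 1e-8), "\n")
cat("DNA loads the active dimer (bound fraction with DNA >> without):",
    summ$final_bound_frac[summ$condition == "atp_dna"] > 0.5, "\n")
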