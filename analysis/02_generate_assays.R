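#!/usr/bin/env Rscript
# Generate the full synthetic assay panel at instrument-like noise (2% of
# the dynamic range) and write every trace as CSV + JSON sidecar under
# results/traces/. Seeds are fixed so the panel is bit-reproducible.

suppressPackageStartupMessages(library(para2kin))
out <- file.path("results", "traces")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

r <- rate_set()
sigma <- 0.02
seed <- 20230504L
save_tr <- function(tr, name) {
  write_trace(tr, file.path(out, paste0(name, ".csv")))
  cat(sprintf("  %-28s %4d points%s\n", name, length(tr$x),
              if (length(tr$flags)) paste0("  [", tr$flags, "]") else ""))
}

cat("Stopped-flow MANT-nucleotide kinetics\n")
for (m in c(3.125, 6.25, 12.5, 25)) {
  save_tr(gen_mant_kinetics(r, "binding", parA2_uM = m / 10, mant_uM = m,
                            noise_sigma = sigma, seed = seed + m),
          sprintf("mant_binding_%guM", m))
}
save_tr(gen_mant_kinetics(r, "dissociation", parA2_uM = 2.5, mant_uM = 5,
                          noise_sigma = sigma, seed = seed + 50),
        "mant_chase")
for (m in c(15.625, 31.25, 62.5)) {
  save_tr(gen_mant_kinetics(r, "exchange", parA2_uM = m / 25, mant_uM = m,
                            noise_sigma = sigma, seed = seed + m),
          sprintf("mant_exchange_%guM", m))
}

cat("Tryptophan conformational switch\n")
for (cn in c("ATP", "ATP+DNA", "ADP", "ATPgS", "no-Mg", "ATP+ParB2",
             "ATP+DNA+ParB2")) {
  save_tr(gen_trp_switch(r, cn, noise_sigma = sigma,
                         seed = seed + nchar(cn)),
          paste0("trp_", gsub("[+]", "_", cn)))
}

cat("EMSA titrations (WT and K124 variants)\n")
for (p in preset("emsa")) {
  save_tr(gen_emsa(preset("emsa", p), noise_sigma = sigma,
                   seed = seed + nchar(p)),
          paste0("emsa_", p))
}

cat("DNA-carpet TIRF time courses\n")
for (cn in c("ATP", "ADP", "ATPgS")) {
  save_tr(gen_carpet_timecourse(r, 1, 360, cn, noise_sigma = sigma,
                                seed = seed + nchar(cn)),
          paste0("carpet_", cn))
}
save_tr(gen_carpet_timecourse(r, 1, 500, "ATP", preincubated = FALSE,
                              noise_sigma = sigma, seed = seed + 99),
        "carpet_ATP_start")

cat("FRAP recovery\n")
save_tr(gen_frap(preset("frap", "carpet-low-density"), duration = 600,
                 noise_sigma = sigma, seed = seed + 7), "frap_low_density")
save_tr(gen_frap(preset("frap", "carpet-parb-1to2"), duration = 1500,
                 noise_sigma = sigma, seed = seed + 8), "frap_parb_1to2")

cat("ATPase assays\n")
for (cn in c("basal", "DNA", "ParB2", "both")) {
  save_tr(gen_atpase(r, cn, t_points_s = seq(0, 3600, 360),
                     noise_sigma = 0.5, seed = seed + nchar(cn)),
          paste0("atpase_", cn))
}
save_tr(gen_atpase(r, "both", parA2_uM = c(0.25, 0.5, 1, 2, 4, 8, 16),
                   noise_sigma = 0.5, seed = seed + 60),
        "atpase_titration")
save_tr(gen_atpase(preset("rates", "k124e"), "DNA",
                   t_points_s = seq(0, 3600, 360), noise_sigma = 0.5,
                   seed = seed + 61), "atpase_k124e")

cat("CD thermal melts\n")
for (p in preset("melt")) {
  save_tr(gen_thermal_melt(preset("melt", p), noise_sigma = 0.05,
                           seed = seed + nchar(p)),
          paste0("melt_", p))
}
cat("done:", length(list.files(out, pattern = "csv$")), "traces\n")
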