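#!/usr/bin/env Rscript
# Global cycle recovery: regenerate the minimum multi-assay dataset
# (binding, exchange, switch, carpet) from the reference rate set and run
# the staged recovery, noiseless and at 2% noise. Writes
# results/recovered_rates.csv.

suppressPackageStartupMessages(library(para2kin))
dir.create("results", showWarnings = FALSE)

truth <- rate_set()
make_dataset <- function(sigma = 0, seed0 = NA_integer_) {
  s <- function(i) if (is.na(seed0)) NA_integer_ else seed0 + i
  cc <- c(6.25, 12.5, 25, 50)
  ce <- c(15.625, 31.25, 62.5)
  list(
    binding = lapply(seq_along(cc), function(i)
      gen_mant_kinetics(truth, "binding", parA2_uM = cc[i] / 25,
                        mant_uM = cc[i], noise_sigma = sigma, seed = s(i))),
    exchange = lapply(seq_along(ce), function(i)
      gen_mant_kinetics(truth, "exchange", parA2_uM = ce[i] / 100,
                        mant_uM = ce[i], noise_sigma = sigma,
                        seed = s(10 + i))),
    switch = list(
      atp = gen_trp_switch(truth, "ATP", noise_sigma = sigma, seed = s(20)),
      atp_dna = gen_trp_switch(truth, "ATP+DNA", noise_sigma = sigma,
                               seed = s(21))),
    carpet = list(
      atp = gen_carpet_timecourse(truth, 1, 360, "ATP", noise_sigma = sigma,
                                  seed = s(30)),
      atpgs = gen_carpet_timecourse(truth, 1, 360, "ATPgS",
                                    noise_sigma = sigma, seed = s(31))))
}

cat("Noiseless recovery:\n")
rec0 <- recover_cycle(make_dataset())
print(rec0)

cat("\nRecovery at 2% noise (seed 101):\n")
rec1 <- recover_cycle(make_dataset(sigma = 0.02, seed0 = 101))

pars <- rec0$diagnostics$parameter
out <- data.frame(parameter = pars,
                  truth = vapply(pars, function(p) truth[[p]], numeric(1)),
                  noiseless = vapply(pars, function(p) rec0$rates[[p]],
                                     numeric(1)),
                  noisy = vapply(pars, function(p) rec1$rates[[p]],
                                 numeric(1)),
                  identifiable = rec0$diagnostics$identifiable)
out$rel_err_noiseless_pct <- 100 * abs(out$noiseless - out$truth) /
  pmax(abs(out$truth), 1e-12)
utils::write.csv(out, "results/recovered_rates.csv", row.names = FALSE)
print(out, row.names = FALSE, digits = 4)

ok <- out$identifiable
cat(sprintf("\nmax noiseless error over identifiable parameters: %.3f%%\n",
            max(out$rel_err_noiseless_pct[ok])))
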