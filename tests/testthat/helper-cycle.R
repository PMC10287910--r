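# reversible MANT-ATP binding only: every downstream branch switched off
binding_only_rates <- function(k1 = 1, k_minus1 = 8) {
  rate_set(k1 = k1, k_minus1 = k_minus1, k2 = 0, k_hyd = 0, kcat = 0,
           k5 = 0, k_minus5 = 0,
           k6_adp_to_atp = 0, k6_adp_to_adp = 0, k6_atp_to_atp = 0)
}

# the standard multi-assay dataset used for cycle recovery
make_cycle_dataset <- function(r, sigma = 0, seed0 = NA_integer_) {
  s <- function(i) if (is.na(seed0)) NA_integer_ else seed0 + i
  cc <- c(6.25, 12.5, 25, 50)
  ce <- c(15.625, 31.25, 62.5)
  list(
    binding = lapply(seq_along(cc), function(i)
      gen_mant_kinetics(r, "binding", parA2_uM = cc[i] / 25, mant_uM = cc[i],
                        noise_sigma = sigma, seed = s(i))),
    exchange = lapply(seq_along(ce), function(i)
      gen_mant_kinetics(r, "exchange", parA2_uM = ce[i] / 100,
                        mant_uM = ce[i], noise_sigma = sigma,
                        seed = s(10 + i))),
    switch = list(
      atp = gen_trp_switch(r, "ATP", noise_sigma = sigma, seed = s(20)),
      atp_dna = gen_trp_switch(r, "ATP+DNA", noise_sigma = sigma,
                               seed = s(21))),
    carpet = list(
      atp = gen_carpet_timecourse(r, 1, 360, "ATP", noise_sigma = sigma,
                                  seed = s(30)),
      atpgs = gen_carpet_timecourse(r, 1, 360, "ATPgS", noise_sigma = sigma,
                                    seed = s(31))))
}

# brute-force grid-search oracle for a 2-parameter exponential rise
# (amplitude x rate), dense grid, minimizing SSE; independent of the fitters
grid_oracle_rise <- function(x, y, n_grid = 200) {
  # the synthetic rise starts at a known zero baseline
  span <- max(x)
  ks <- exp(seq(log(0.1 / span), log(20 / span), length.out = n_grid))
  as <- seq(0.5 * diff(range(y)), 2 * diff(range(y)), length.out = n_grid)
  best <- c(k = NA_real_, sse = Inf)
  for (k in ks) {
    base <- 1 - exp(-k * x)
    for (a in as) {
      sse <- sum((y - a * base)^2)
      if (sse < best[["sse"]]) best <- c(k = k, sse = sse)
    }
  }
  list(k = best[["k"]], k_spacing = ks[2] / ks[1] - 1)
}

# grid-search oracle for the hyperbolic isotherm (KD x ymax)
grid_oracle_hyperbola <- function(x, y, n_grid = 200) {
  kds <- exp(seq(log(min(x) / 5), log(max(x) * 5), length.out = n_grid))
  ymaxs <- seq(0.5 * max(y), 2 * max(y), length.out = n_grid)
  best <- c(kd = NA_real_, sse = Inf)
  for (kd in kds) {
    h <- x / (kd + x)
    for (ym in ymaxs) {
      sse <- sum((y - ym * h)^2)
      if (sse < best[["sse"]]) best <- c(kd = kd, sse = sse)
    }
  }
  list(kd = best[["kd"]], kd_spacing = kds[2] / kds[1] - 1)
}

# minimal synthetic kymograph object for the spatial metrics
synthetic_kymograph <- function(time, bound, L = 2) {
  N <- ncol(bound)
  structure(list(time = time, bound = bound,
                 cyto = matrix(0, nrow(bound), N),
                 x = (seq_len(N) - 0.5) * L / N,
                 config = list(L = L, N = N),
                 engine = "synthetic"),
            class = "para_kymograph")
}
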