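r_default <- rate_set()

test_that("noise is seed-reproducible and zero-noise output deterministic", {
  a <- gen_emsa(hill_params(46, 4), noise_sigma = 0.02, seed = 1)
  b <- gen_emsa(hill_params(46, 4), noise_sigma = 0.02, seed = 1)
  c <- gen_emsa(hill_params(46, 4), noise_sigma = 0.02, seed = 2)
  expect_identical(a$y, b$y)
  expect_false(identical(a$y, c$y))
  d1 <- gen_frap(frap_params(0.64, 0.23, 0.13, 2.3, 121))
  d2 <- gen_frap(frap_params(0.64, 0.23, 0.13, 2.3, 121))
  expect_identical(d1$y, d2$y)
  expect_error(gen_emsa(hill_params(46, 4), noise_sigma = 0.02), "seed")
})

test_that("MANT binding kobs falls in the measured stopped-flow range", {
  tr <- gen_mant_kinetics(r_default, "binding", parA2_uM = 1.25, mant_uM = 25)
  kobs <- fit_single_exponential(tr, "rise")$estimates[["kobs"]]
  expect_gt(kobs, 0.09)
  expect_lt(kobs, 0.13)
})

test_that("flat binding trace when association is off", {
  r0 <- binding_only_rates(k1 = 0, k_minus1 = 8)
  tr <- gen_mant_kinetics(r0, "binding", parA2_uM = 1.25, mant_uM = 25)
  expect_true(all(tr$y == 0))
  expect_error(fit_single_exponential(tr, "rise"), NA)
  expect_match(fit_single_exponential(tr, "rise")$flags, "flat")
})

test_that("MANT chase is multiphasic: fast release phase, slow retained pool", {
  tr <- gen_mant_kinetics(r_default, "dissociation", parA2_uM = 2.5,
                          mant_uM = 5)
  f <- fit_two_phase_decay(tr)
  expect_true(f$converged)
  # fast phase = closed-dimer exit (k_minus1 + k2); slow phase is the
  # remodeled pool draining through hydrolysis
  expect_equal(f$estimates[["k_fast"]], r_default$k_minus1 + r_default$k2,
               tolerance = 0.1)
  expect_lt(f$estimates[["k_slow"]], 0.02)
  expect_lt(f$estimates[["k_slow"]], f$estimates[["k_fast"]])
})

test_that("exchange protocol kobs is linear with slope = exchange constant", {
  concs <- c(15.625, 31.25, 62.5)
  kobs <- vapply(concs, function(m) {
    tr <- gen_mant_kinetics(r_default, "exchange", parA2_uM = m / 25,
                            mant_uM = m)
    fit_single_exponential(tr, "rise")$estimates[["kobs"]]
  }, numeric(1))
  pf <- pseudo_first_order(data.frame(conc = concs, kobs = kobs))
  expect_equal(pf$estimates[["kon"]], r_default$k6_adp_to_atp,
               tolerance = 0.05)
  expect_gt(pf$estimates[["r_squared"]], 0.99)
})

test_that("tryptophan switch reproduces the measured condition fingerprint", {
  atp <- gen_trp_switch(r_default, "ATP")
  k_atp <- fit_single_exponential(atp, "rise",
                                  exclude_lag = TRUE)$estimates[["kobs"]]
  expect_gt(k_atp, 0.015)
  expect_lt(k_atp, 0.018)

  dna <- gen_trp_switch(r_default, "ATP+DNA")
  k_dna <- fit_single_exponential(dna, "rise",
                                  exclude_lag = TRUE)$estimates[["kobs"]]
  expect_gt(k_dna, 0.03)
  expect_lt(k_dna, 0.07)
  # DNA more than doubles the conformational-signal plateau
  expect_gt(max(dna$y) - 1, 2 * (max(atp$y) - 1))

  # ParB2 leaves the rates essentially unchanged
  parb <- gen_trp_switch(r_default, "ATP+ParB2")
  k_parb <- fit_single_exponential(parb, "rise",
                                   exclude_lag = TRUE)$estimates[["kobs"]]
  expect_equal(k_parb, k_atp, tolerance = 0.05)

  # controls: no-Mg is monotone non-increasing; ADP and ATPgS stay flat
  nomg <- gen_trp_switch(r_default, "no-Mg")
  expect_true(all(diff(nomg$y) <= 1e-12))
  adp <- gen_trp_switch(r_default, "ADP")
  expect_lt(max(adp$y) - min(adp$y), 0.001 + 2e-4 * 400)
})

test_that("EMSA titration passes through its defining midpoint", {
  tr <- gen_emsa(hill_params(46, 4), protein_nM = c(10, 20, 46, 100, 300,
                                                    600, 900, 1200))
  expect_equal(tr$y[tr$x == 46], 0.5)
  # non-cooperative limit is a hyperbola
  h <- gen_emsa(hill_params(100, 1), protein_nM = c(10, 50, 100, 200, 400,
                                                    800))
  expect_equal(h$y[h$x == 100], 0.5)
  # ADP condition never reaches the plateau within the titration range
  adp <- gen_emsa(preset("emsa", "wt-adp"))
  expect_lt(max(adp$y), 1)
  # low-range titration is flagged for the downstream fit
  lo <- gen_emsa(hill_params(5000, 2), protein_nM = c(10, 20, 40, 80, 160,
                                                      320))
  expect_match(lo$flags, "below KD")
})

test_that("EMSA clipping under noise is counted, never silent", {
  tr <- gen_emsa(hill_params(46, 4), noise_sigma = 0.2, seed = 3)
  expect_true(all(tr$y >= 0 & tr$y <= 1))
  expect_gt(tr$n_clipped, 0)
})

test_that("carpet time course: association 0.05/s, wash decay 0.1/s", {
  tr <- gen_carpet_timecourse(r_default, protein_uM = 1, t_switch = 360)
  assoc <- fit_single_exponential(
    data.frame(x = tr$x[tr$x <= 360], y = tr$y[tr$x <= 360]), "rise")
  expect_equal(assoc$estimates[["kobs"]], 0.05, tolerance = 0.02)
  wash <- fit_two_phase_decay(
    data.frame(x = tr$x[tr$x >= 360] - 360, y = tr$y[tr$x >= 360]))
  expect_equal(wash$estimates[["k_fast"]], 0.1, tolerance = 0.02)
  expect_equal(wash$estimates[["k_slow"]], r_default$k_minus3,
               tolerance = 0.02)
})

test_that("carpet controls: ADP negligible, ATPgS slow, ATP-start delayed", {
  adp <- gen_carpet_timecourse(r_default, 1, 360, condition = "ADP")
  expect_lt(max(adp$y), 0.05)
  gs <- gen_carpet_timecourse(r_default, 1, 360, condition = "ATPgS")
  gw <- fit_single_exponential(
    data.frame(x = gs$x[gs$x >= 360] - 360, y = gs$y[gs$x >= 360]), "decay")
  expect_equal(gw$estimates[["kobs"]], r_default$k_minus3, tolerance = 0.05)
  # ATP-start: remodeling-limited supply delays the rise by about a minute
  st <- gen_carpet_timecourse(r_default, 1, t_switch = 500,
                              preincubated = FALSE, duration = 600)
  pre <- gen_carpet_timecourse(r_default, 1, t_switch = 500, duration = 600)
  plateau_st <- max(st$y[st$x <= 500])
  plateau_pre <- max(pre$y[pre$x <= 500])
  expect_lt(st$y[st$x == 60] / plateau_st, 0.5)
  expect_gt(pre$y[pre$x == 60] / plateau_pre, 0.9)
  expect_error(gen_carpet_timecourse(r_default, 1, t_switch = -5), "positive")
})

test_that("FRAP curve starts at zero and recovers to 1 - immobile", {
  p <- frap_params(0.64, 0.23, 0.13, 2.3, 121)
  tr <- gen_frap(p, duration = 600)
  expect_equal(tr$y[1], 0, tolerance = 1e-12)
  expect_equal(max(tr$y), 1 - 0.13, tolerance = 0.01)
  # fully immobile spot never recovers
  flat <- gen_frap(frap_params(0, 0, 1, 2.3, 121))
  expect_true(all(abs(flat$y) < 1e-12))
  expect_error(frap_params(0.5, 0.3, 0.1, 100, 10), "tau_fast")
  expect_error(frap_params(0.8, 0.5, 0.2, 1, 10), "sum")
})

test_that("ATPase stimulation ratios follow the cofactor factors", {
  r <- r_default
  y <- vapply(c("basal", "DNA", "ParB2", "both"), function(cn) {
    gen_atpase(r, cn, t_points_s = c(0, 600))$y[2]
  }, numeric(1))
  expect_equal(unname(y[["DNA"]] / y[["basal"]]), r$stim_dna,
               tolerance = 0.02)
  expect_equal(unname(y[["ParB2"]] / y[["basal"]]), r$stim_parb,
               tolerance = 0.02)
  expect_equal(unname(y[["both"]] / y[["basal"]]), r$stim_both,
               tolerance = 0.02)
})

test_that("ATPase titration saturates by substrate depletion; K124E is dead", {
  tr <- gen_atpase(r_default, "both", parA2_uM = c(0.5, 1, 2, 4, 8, 16, 32),
                   fixed_time_s = 1800)
  expect_lt(max(tr$y), 100 + 1e-9)
  gains <- diff(tr$y)
  expect_lt(gains[length(gains)], gains[1])  # flattening
  dead <- gen_atpase(preset("rates", "k124e"), "DNA",
                     t_points_s = c(0, 600, 1800))
  expect_true(all(dead$y == 0))
})

test_that("thermal melt midpoint sits at Tm; equal baselines give a flat trace", {
  m <- gen_thermal_melt(melt_params(44, 1.8))
  mid <- (m$params$theta_folded + m$params$theta_unfolded) / 2
  expect_equal(stats::approx(m$x, m$y, xout = 44)$y, mid, tolerance = 1e-9)
  flat <- gen_thermal_melt(melt_params(44, 1.8, theta_folded = -5,
                                       theta_unfolded = -5))
  expect_true(all(flat$y == -5))
  out <- gen_thermal_melt(melt_params(70, 1.8))
  expect_match(out$flags, "outside")
})
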