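test_that("single-exponential fit is exact on its own model class", {
  tt <- seq(0, 100, 0.5)
  rise <- data.frame(x = tt, y = 1 - exp(-0.05 * tt))
  f <- fit_single_exponential(rise, "rise")
  expect_equal(f$estimates[["kobs"]], 0.05, tolerance = 1e-6)
  decay <- data.frame(x = tt, y = 0.2 + 0.8 * exp(-0.11 * tt))
  g <- fit_single_exponential(decay, "decay")
  expect_equal(g$estimates[["kobs"]], 0.11, tolerance = 1e-6)
  flat <- data.frame(x = tt, y = rep(0.3, length(tt)))
  expect_match(fit_single_exponential(flat, "rise")$flags, "flat trace")
  expect_error(fit_single_exponential(data.frame(x = 1:5, y = 1:5), "rise"),
               "20 points")
})

test_that("noisy rise agrees with the brute-force grid-search oracle", {
  tt <- seq(0, 100, 0.5)
  set.seed(77)
  y <- 1 - exp(-0.05 * tt) + stats::rnorm(length(tt), 0, 0.02)
  f <- fit_single_exponential(data.frame(x = tt, y = y), "rise")
  o <- grid_oracle_rise(tt, y)
  expect_equal(f$estimates[["kobs"]], o$k, tolerance = o$k_spacing)
})

test_that("lag exclusion reports the fitted window", {
  tt <- seq(0, 200, 0.5)
  y <- ifelse(tt < 20, 0, 1 - exp(-0.05 * (tt - 20)))
  f <- fit_single_exponential(data.frame(x = tt, y = y), "rise",
                              exclude_lag = TRUE)
  expect_gt(f$window[1], 5)
  expect_equal(f$estimates[["kobs"]], 0.05, tolerance = 0.05)
})

test_that("two-phase decay separates its phases and collapses when right", {
  tt <- seq(0, 600, 0.5)
  y <- 0.6 * exp(-0.43 * tt) + 0.4 * exp(-0.008 * tt)
  f <- fit_two_phase_decay(data.frame(x = tt, y = y))
  expect_equal(f$estimates[["k_fast"]], 0.43, tolerance = 0.05)
  expect_equal(f$estimates[["k_slow"]], 0.008, tolerance = 0.05)
  single <- data.frame(x = tt, y = exp(-0.05 * tt))
  expect_match(fit_two_phase_decay(single)$flags, "collapsed")
})

test_that("pseudo-first-order line returns kon, koff and their ratio", {
  d <- data.frame(conc = c(3.125, 6.25, 12.5, 25),
                  kobs = 0.0035 * c(3.125, 6.25, 12.5, 25) + 0.028)
  f <- pseudo_first_order(d)
  expect_equal(f$estimates[["kon"]], 0.0035, tolerance = 1e-10)
  expect_equal(f$estimates[["koff"]], 0.028, tolerance = 1e-10)
  expect_equal(f$estimates[["kd_uM"]], 8, tolerance = 1e-9)
  # two exactly collinear points give the exact line
  two <- pseudo_first_order(data.frame(conc = c(10, 20),
                                       kobs = c(0.1, 0.15)))
  expect_equal(two$estimates[["kon"]], 0.005)
  expect_equal(two$estimates[["koff"]], 0.05)
  neg <- pseudo_first_order(data.frame(conc = c(1, 2, 3),
                                       kobs = c(0.009, 0.020, 0.031)))
  expect_equal(neg$estimates[["koff"]], 0)
  expect_match(neg$flags, "negative intercept")
})

test_that("Hill fit recovers cooperative, hyperbolic and variant titrations", {
  f <- fit_hill(gen_emsa(hill_params(46, 4)))
  expect_equal(f$estimates[["kd"]], 46, tolerance = 0.01)
  expect_equal(f$estimates[["n"]], 4, tolerance = 0.02)
  h <- fit_hill(gen_emsa(hill_params(100, 1),
                         protein_nM = exp(seq(log(5), log(2000), length.out = 8))))
  expect_equal(h$estimates[["n"]], 1, tolerance = 0.02)
  e <- fit_hill(gen_emsa(preset("emsa", "k124e")))
  expect_equal(e$estimates[["kd"]], 452, tolerance = 0.01)
})

test_that("Hill fit with n fixed to 1 equals the hyperbolic fit", {
  tr <- gen_emsa(hill_params(300, 1),
                 protein_nM = c(20, 50, 100, 200, 400, 700))
  hf <- fit_hill(tr)
  hy <- fit_hyperbolic_kd(tr)
  expect_match(paste(hf$flags, collapse = " "), "n fixed to 1")
  expect_equal(hf$estimates[["kd"]], hy$estimates[["kd"]], tolerance = 0.01)
})

test_that("hyperbolic isotherm recovers an 11 uM nucleotide affinity", {
  conc <- c(1, 2.5, 5, 10, 20, 40, 80)
  iso <- para_trace(conc, conc / (11 + conc), "mant_isotherm",
                    x_unit = "mant_uM", y_unit = "rel_fluor")
  f <- fit_hyperbolic_kd(iso)
  expect_equal(f$estimates[["kd"]], 11, tolerance = 1e-6)
  sat <- para_trace(conc * 100, (conc * 100) / (11 + conc * 100), "x")
  expect_match(fit_hyperbolic_kd(sat)$flags, "saturated")
})

test_that("noisy hyperbolic fit agrees with its grid-search oracle", {
  conc <- c(1, 2.5, 5, 10, 20, 40, 80)
  set.seed(5)
  y <- conc / (11 + conc) + stats::rnorm(length(conc), 0, 0.02)
  f <- fit_hyperbolic_kd(data.frame(x = conc, y = y))
  o <- grid_oracle_hyperbola(conc, y)
  expect_equal(f$estimates[["kd"]], o$kd, tolerance = o$kd_spacing)
})

test_that("FRAP fit recovers both published parameter sets within 5%", {
  f1 <- fit_frap(gen_frap(frap_params(0.64, 0.23, 0.13, 2.3, 121),
                          duration = 600))
  expect_equal(f1$estimates[["tau_fast"]], 2.3, tolerance = 0.05)
  expect_equal(f1$estimates[["tau_slow"]], 121, tolerance = 0.05)
  expect_equal(f1$estimates[["immobile"]], 0.13, tolerance = 0.05)
  f2 <- fit_frap(gen_frap(frap_params(0.40, 0.25, 0.35, 8.2, 308),
                          duration = 1500))
  expect_equal(f2$estimates[["tau_fast"]], 8.2, tolerance = 0.05)
  expect_equal(f2$estimates[["tau_slow"]], 308, tolerance = 0.05)
  # ParB2 slows exchange: half-recovery time strictly larger
  half_time <- function(p, dur) {
    tr <- gen_frap(p, duration = dur)
    asym <- 1 - p$fraction_immobile
    tr$x[which(tr$y >= asym / 2)[1]]
  }
  expect_gt(half_time(frap_params(0.40, 0.25, 0.35, 8.2, 308), 1500),
            half_time(frap_params(0.64, 0.23, 0.13, 2.3, 121), 600))
  # fully immobile curve: immobile ~ 1, time constants unidentifiable
  f3 <- fit_frap(gen_frap(frap_params(0, 0, 1, 2.3, 121)))
  expect_false(f3$converged)
  expect_equal(f3$estimates[["immobile"]], 1, tolerance = 1e-6)
})

test_that("Boltzmann melt fit recovers apo and ATP midpoints", {
  expect_equal(fit_melt(gen_thermal_melt(melt_params(44, 1.8)))$estimates[["tm"]],
               44, tolerance = 0.001)
  expect_equal(fit_melt(gen_thermal_melt(melt_params(53, 1.8)))$estimates[["tm"]],
               53, tolerance = 0.001)
  flat <- gen_thermal_melt(melt_params(44, 1.8, theta_folded = -5,
                                       theta_unfolded = -5))
  expect_match(fit_melt(flat)$flags, "unidentifiable")
  # the symmetric sigmoid midpoint is the halfway-ellipticity temperature
  m <- gen_thermal_melt(melt_params(48, 2.5))
  fm <- fit_melt(m)
  mid <- (fm$estimates[["theta_folded"]] + fm$estimates[["theta_unfolded"]]) / 2
  expect_equal(stats::approx(m$y, m$x, xout = mid)$y,
               fm$estimates[["tm"]], tolerance = 0.01)
})

test_that("fitters are invariant to uniform y-scaling", {
  tt <- seq(0, 100, 0.5)
  d <- data.frame(x = tt, y = 1 - exp(-0.05 * tt))
  d10 <- transform(d, y = 10 * y)
  f1 <- fit_single_exponential(d, "rise")
  f10 <- fit_single_exponential(d10, "rise")
  expect_equal(f10$estimates[["kobs"]], f1$estimates[["kobs"]],
               tolerance = 1e-8)
  expect_equal(f10$estimates[["amplitude"]],
               10 * f1$estimates[["amplitude"]], tolerance = 1e-8)
  fr <- gen_frap(frap_params(0.64, 0.23, 0.13, 2.3, 121), duration = 400)
  fr2 <- fr; fr2$y <- fr$y * 3
  expect_equal(fit_frap(fr2)$estimates[["tau_fast"]],
               fit_frap(fr)$estimates[["tau_fast"]], tolerance = 1e-5)
})

test_that("binding kobs is linear in substrate at zero noise (R^2 > 0.99)", {
  r <- rate_set()
  concs <- c(3.125, 6.25, 12.5, 25)
  kobs <- vapply(concs, function(m) {
    tr <- gen_mant_kinetics(r, "binding", parA2_uM = m / 10, mant_uM = m)
    fit_single_exponential(tr, "rise")$estimates[["kobs"]]
  }, numeric(1))
  pf <- pseudo_first_order(data.frame(conc = concs, kobs = kobs))
  expect_gt(pf$estimates[["r_squared"]], 0.99)
  # and the implied affinity is the ~8 uM nucleotide KD
  expect_equal(pf$estimates[["kd_uM"]], 8, tolerance = 0.3)
})
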