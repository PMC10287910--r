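demo_cfg <- preset("spatial", "tugofwar-demo")

test_that("spatial config enforces its geometric invariants", {
  expect_error(spatial_config(L = 0), "length")
  expect_error(spatial_config(N = 20), "50")
  expect_error(spatial_config(d_cyto = -1), "diffusion")
  expect_error(spatial_config(focus_pos = 1.2), "0, 1")
  expect_error(spatial_config(focus_stim = 0.5), ">= 1")
})

test_that("SSA engine conserves total ParA2 exactly and reproduces by seed", {
  cfg <- spatial_config(rates = rate_set(coop_omega = 100), t_end = 40,
                        N = 50, dt_record = 2, copies = 400, focus_stim = 40,
                        focus_width = 0.2, site_capacity = 40, d_cyto = 0.3,
                        nucleoid_sites_uM = 0.3, seed = 5)
  k <- simulate_cell(cfg, engine = "ssa")
  tot <- kymograph_total(k)
  expect_true(all(tot == tot[1]))
  k2 <- simulate_cell(cfg, engine = "ssa")
  expect_identical(k$bound, k2$bound)
})

test_that("PDE engine conserves mass to tolerance and rejects Courant violations", {
  cfg <- demo_cfg
  cfg$t_end <- 200
  k <- simulate_cell(cfg, engine = "pde")
  tot <- kymograph_total(k)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  expect_error(simulate_cell(cfg, engine = "pde", pde_method = "euler",
                             pde_dt = 1), "Courant")
})

test_that("PDE and SSA ensemble agree in the linear high-copy regime", {
  cfg <- spatial_config(rates = rate_set(coop_omega = 1), t_end = 10, N = 50,
                        dt_record = 5, copies = 5000, focus_stim = 1,
                        site_capacity = 10000, d_cyto = 0.05,
                        nucleoid_sites_uM = 0.3, seed = 1)
  runs <- vapply(1:20, function(i) {
    cfg$seed <- 100 + i
    k <- simulate_cell(cfg, engine = "ssa")
    rowSums(k$bound)
  }, numeric(3))
  pde <- simulate_cell(cfg, engine = "pde", init_bias = 0, init_bound = 0)
  for (j in 2:3) {
    m <- mean(runs[j, ])
    se <- stats::sd(runs[j, ]) / sqrt(ncol(runs))
    expect_lt(abs(m - sum(pde$bound[j, ])), 3 * se)
  }
})

test_that("the shipped tug-of-war cell oscillates pole to pole", {
  k <- simulate_cell(demo_cfg, engine = "pde", init_bias = 0.5)
  p <- measure_period(k)
  expect_true(p$oscillatory)
  expect_gt(p$period_s, 60)
  expect_lt(p$period_s, 900)
  tr <- measure_transit(k)
  expect_true(tr$oscillatory)
  expect_gt(tr$n_crossings, 2)
  # the asymmetry index alternates sign with the measured period
  ai0 <- asymmetry_index(k, 600)
  ai_half <- asymmetry_index(k, 600 + p$period_s / 2)
  ai_full <- asymmetry_index(k, 600 + p$period_s)
  expect_lt(ai0 * ai_half, 0)
  expect_gt(ai0 * ai_full, 0)
})

test_that("focus knockout abolishes the oscillation", {
  cfg <- demo_cfg
  cfg$focus_stim <- 1
  k <- simulate_cell(cfg, engine = "pde", init_bias = 0.5)
  p <- measure_period(k, min_periods = 2)
  expect_false(p$oscillatory)
})

test_that("oscillation statistic never decreases along a stimulation scan", {
  stats <- vapply(c(1, 5, 10, 20, 40), function(fs) {
    cfg <- demo_cfg
    cfg$focus_stim <- fs
    cfg$t_end <- 1500
    k <- simulate_cell(cfg, engine = "pde", init_bias = 0.5)
    p <- measure_period(k, min_periods = 2)
    if (is.na(p$peak_acf)) 0 else p$peak_acf
  }, numeric(1))
  expect_true(all(diff(stats) >= -1e-9))
})

test_that("time-averaged bound density is midcell-symmetric with a fixed focus", {
  # symmetric geometry, stochastic engine, >= 10 seeds
  ai <- vapply(1:10, function(s) {
    cfg <- spatial_config(rates = rate_set(coop_omega = 10), t_end = 60,
                          N = 50, dt_record = 5, copies = 400,
                          focus_stim = 10, focus_width = 0.2,
                          site_capacity = 40, d_cyto = 0.3,
                          nucleoid_sites_uM = 1, seed = 400 + s)
    k <- simulate_cell(cfg, engine = "ssa")
    mean(vapply(seq(20, 60, 10), function(t) asymmetry_index(k, t),
                numeric(1)))
  }, numeric(1))
  se <- stats::sd(ai) / sqrt(length(ai))
  expect_lt(abs(mean(ai)), 3 * se + 1e-12)
})

test_that("period metric matches synthetic kymographs and a periodogram oracle", {
  tt <- seq(0, 1800, 2)
  N <- 50
  # square-wave alternation, period 300 s
  sq <- t(vapply(tt, function(t) {
    row <- numeric(N)
    if (floor(t / 150) %% 2 == 0) row[1:25] <- 10 else row[26:50] <- 10
    row
  }, numeric(N)))
  k <- synthetic_kymograph(tt, sq)
  p <- measure_period(k)
  expect_true(p$oscillatory)
  expect_equal(p$period_s, 300, tolerance = 0.05)

  # noisy sinusoid, period 240 s
  set.seed(11)
  phase <- sin(2 * pi * tt / 240)
  sn <- outer(phase, c(rep(1, 25), rep(-1, 25))) * 5 + 10 +
    matrix(stats::rnorm(length(tt) * N, 0, 0.5), length(tt), N)
  sn[sn < 0] <- 0
  p2 <- measure_period(synthetic_kymograph(tt, sn))
  expect_true(p2$oscillatory)
  expect_equal(p2$period_s, 240, tolerance = 10 / 240)

  # agreement with a periodogram oracle on random sinusoidal kymographs
  set.seed(21)
  for (i in 1:20) {
    per <- stats::runif(1, 150, 500)
    ph <- sin(2 * pi * tt / per)
    bb <- outer(ph, c(rep(1, 25), rep(-1, 25))) * 4 + 8
    bb[bb < 0] <- 0
    kk <- synthetic_kymograph(tt, bb)
    est <- measure_period(kk, n_surrogates = 30)
    sig <- rowSums(bb[, 1:25]) - rowSums(bb[, 26:50])
    sp <- stats::spec.pgram(stats::ts(sig - mean(sig), deltat = 2),
                            plot = FALSE, taper = 0, detrend = FALSE)
    oracle <- 1 / sp$freq[which.max(sp$spec)]
    expect_equal(est$period_s, oracle, tolerance = 0.15)
  }
})

test_that("transit metric matches closed-form synthetic motions", {
  tt <- seq(0, 3200, 2)
  N <- 50
  # instantaneous square-wave switch: transit ~ one frame interval
  sq <- t(vapply(tt, function(t) {
    row <- numeric(N)
    if (floor(t / 150) %% 2 == 0) row[1:10] <- 10 else row[41:50] <- 10
    row
  }, numeric(N)))
  tr <- measure_transit(synthetic_kymograph(tt, sq))
  expect_true(tr$oscillatory)
  expect_lte(tr$transit_s, 4 + 1e-9)

  # linearly translating Gaussian: transit = 0.5 L / speed
  L <- 2
  speed <- 0.01  # um/s, 400 s per full sweep of a 2 um cell (period 800 s)
  x <- (seq_len(N) - 0.5) * L / N
  tri <- function(t) {
    ph <- (t %% 400) / 400
    if (floor(t / 400) %% 2 == 0) 0.1 + 1.8 * ph else 1.9 - 1.8 * ph
  }
  gg <- t(vapply(tt, function(t) {
    mu <- tri(t)
    stats::dnorm(x, mu, 0.15)
  }, numeric(N)))
  trg <- measure_transit(synthetic_kymograph(tt, gg, L = L))
  # centre crosses 0.5 um -> 1.5 um at 1.8 um per 400 s: 222 s expected
  expect_equal(trg$transit_s, 0.5 * L / (1.8 / 400), tolerance = 0.08)

  # event-listing oracle on a few random triangle-wave kymographs
  set.seed(33)
  for (i in 1:5) {
    per <- stats::runif(1, 300, 700)
    trf <- function(t) {
      ph <- (t %% per) / per
      if (floor(t / per) %% 2 == 0) 0.1 + 1.8 * ph else 1.9 - 1.8 * ph
    }
    gk <- t(vapply(tt, function(t) stats::dnorm(x, trf(t), 0.12),
                   numeric(N)))
    est <- measure_transit(synthetic_kymograph(tt, gk, L = L))
    expect_equal(est$transit_s, (0.5 * L) / (1.8 / per), tolerance = 0.1)
  }
})

test_that("asymmetry index hits its closed-form anchors", {
  tt <- c(0, 1, 2)
  left <- matrix(0, 3, 50); left[, 1:25] <- 4
  expect_equal(asymmetry_index(synthetic_kymograph(tt, left), 1), 1)
  unif <- matrix(3, 3, 50)
  expect_equal(asymmetry_index(synthetic_kymograph(tt, unif), 1), 0)
  zero <- matrix(0, 3, 50)
  z <- asymmetry_index(synthetic_kymograph(tt, zero), 1)
  expect_true(is.na(z))
  expect_true(attr(z, "undefined"))
  expect_error(asymmetry_index(synthetic_kymograph(tt, unif), 99),
               "outside")
})
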