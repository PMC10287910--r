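test_that("reversible binding relaxes to the closed-form equilibrium", {
  r <- binding_only_rates()          # KD = 8 uM
  sch <- assemble_scheme(r, assay_condition("ATP"))
  # tracer-level protein so substrate depletion is negligible
  traj <- integrate_scheme(sch, species_state(c(D = 1e-5, mATP = 25)),
                           seq(0, 8, by = 0.01))
  bound <- unname(traj$state[nrow(traj$state), "mDT"] / 1e-5)
  expect_equal(bound, 25 / (8 + 25), tolerance = 1e-6)
})

test_that("total dimer is conserved in every ODE run", {
  r <- rate_set()
  conds <- list(assay_condition("ATP"),
                assay_condition("ATP", dna = TRUE),
                assay_condition("ATP", dna = TRUE, parb = TRUE),
                assay_condition("ADP"),
                assay_condition("ATPgS", dna = TRUE))
  for (cn in conds) {
    init <- species_state(c(D = 0.625, ATP = 50, mATP = 25, ADP = 5,
                            sites = 5, ParB = if (cn$parb) 1 else 0))
    traj <- integrate_scheme(assemble_scheme(r, cn), init, seq(0, 120, 1))
    expect_lt(max(conservation_error(traj)), 1e-8)
  }
})

test_that("all-zero rates give a constant trajectory", {
  r <- binding_only_rates(k1 = 0, k_minus1 = 0)
  r$k_minus1 <- 0
  sch <- assemble_scheme(r, assay_condition("ATP"))
  init <- species_state(c(D = 1, mATP = 10))
  traj <- integrate_scheme(sch, init, seq(0, 10, 1))
  expect_true(all(apply(traj$state, 2, function(cc) all(cc == cc[1]))))
})

test_that("excess-chase decay follows exp(-k_minus1 t) to <1%", {
  r <- binding_only_rates()
  sch <- assemble_scheme(r, assay_condition("ATP"))
  eq <- integrate_scheme(sch, species_state(c(D = 0.05, mATP = 5)),
                         seq(0, 60, 0.5))
  start <- eq$state[nrow(eq$state), ]
  start[["ATP"]] <- 1000
  tt <- seq(0, 0.6, by = 0.002)
  chase <- integrate_scheme(sch, start, tt)
  # a small labelled-bound residue persists (the label competes at ~0.5%
  # occupancy against the chase), so compare the fitted decay RATE
  f <- fit_single_exponential(
    data.frame(x = tt, y = chase$state[, "mDT"]), "decay")
  expect_lt(abs(f$estimates[["kobs"]] - r$k_minus1) / r$k_minus1, 0.01)
})

test_that("hydrolysis makes ADP-equivalents non-decreasing", {
  r <- rate_set(k6_adp_to_atp = 0, k6_adp_to_adp = 0, k6_atp_to_atp = 0)
  sch <- assemble_scheme(r, assay_condition("ATP", dna = TRUE))
  init <- species_state(c(D = 0.625, ATP = 100, sites = 5))
  traj <- integrate_scheme(sch, init, seq(0, 600, 2))
  adp <- nucleotide_totals(traj)$adp_total
  expect_true(all(diff(adp) > -1e-9))
  # and the nucleotide grand total is conserved
  tot <- rowSums(nucleotide_totals(traj)[, c("atp_total", "adp_total")])
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
})

test_that("bad grids and initial states are rejected", {
  sch <- assemble_scheme(rate_set(), assay_condition("ATP"))
  init <- species_state(c(D = 1))
  expect_error(integrate_scheme(sch, init, c(1, 2)), "start at 0")
  expect_error(integrate_scheme(sch, init, c(0, 1, 1)), "increasing")
})
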