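test_that("same seed reproduces the exact trajectory, different seeds differ", {
  sch <- assemble_scheme(binding_only_rates(), assay_condition("ATP"))
  a <- sample_ssa(sch, c(D = 200, mATP = 5000), t_end = 1, seed = 42)
  b <- sample_ssa(sch, c(D = 200, mATP = 5000), t_end = 1, seed = 42)
  c <- sample_ssa(sch, c(D = 200, mATP = 5000), t_end = 1, seed = 43)
  expect_identical(a$state, b$state)
  expect_false(identical(a$state, c$state))
})

test_that("empty initial state fires no reactions and is flagged", {
  sch <- assemble_scheme(binding_only_rates(), assay_condition("ATP"))
  tr <- sample_ssa(sch, c(D = 0), t_end = 1, seed = 1)
  expect_true(attr(tr, "exhausted"))
  expect_true(all(tr$state == 0))
})

test_that("SSA ensemble mean matches the ODE at 1000 copies within 3 SE", {
  sch <- assemble_scheme(binding_only_rates(), assay_condition("ATP"))
  grid <- c(0, 0.5, 1, 2)
  n <- 200
  runs <- vapply(seq_len(n), function(i) {
    s <- sample_ssa(sch, c(D = 1000, mATP = 25000), t_end = 2, seed = 1000 + i,
                    record_grid = grid)
    s$state[, "mDT"]
  }, numeric(length(grid)))
  ode <- integrate_scheme(sch, species_state(c(D = 1, mATP = 25)), grid)
  for (j in 2:length(grid)) {
    m <- mean(runs[j, ])
    se <- stats::sd(runs[j, ]) / sqrt(n)
    expect_lt(abs(m - 1000 * ode$state[j, "mDT"]), 3 * se)
  }
})
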