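test_that("hydrolysis rate carries the condition's fold-stimulation", {
  r <- rate_set()
  for (cond in list(list(dna = FALSE, parb = FALSE, f = 1),
                    list(dna = TRUE, parb = FALSE, f = r$stim_dna),
                    list(dna = FALSE, parb = TRUE, f = r$stim_parb),
                    list(dna = TRUE, parb = TRUE, f = r$stim_both))) {
    sch <- assemble_scheme(r, assay_condition("ATP", dna = cond$dna,
                                              parb = cond$parb))
    expect_equal(scheme_rate(sch, "hydrolyze_DS"), r$k_hyd * cond$f)
    if (cond$dna) {
      expect_equal(scheme_rate(sch, "hydrolyze_release_B"),
                   r$k_hyd * cond$f)
    }
  }
  # the 8-fold stimulation with both cofactors, relative to basal
  s_basal <- assemble_scheme(r, assay_condition("ATP"))
  s_both <- assemble_scheme(r, assay_condition("ATP", dna = TRUE, parb = TRUE))
  expect_equal(scheme_rate(s_both, "hydrolyze_DS") /
                 scheme_rate(s_basal, "hydrolyze_DS"), 8)
})

test_that("no-nucleotide condition leaves the apo dimer inert", {
  sch <- assemble_scheme(rate_set(), assay_condition("none"))
  expect_length(sch$reactions, 0)
  traj <- integrate_scheme(sch, species_state(c(D = 1)), seq(0, 10, 1))
  expect_true(all(traj$state[, "D"] == 1))
})

test_that("ATPgS removes the hydrolysis branch but keeps DNA binding", {
  r <- rate_set()
  sch <- assemble_scheme(r, assay_condition("ATPgS", dna = TRUE))
  nms <- vapply(sch$reactions, `[[`, "", "name")
  expect_false(any(grepl("hydrolyze", nms)))
  expect_true(any(grepl("load_DS", nms)))
  expect_true(any(grepl("unload_B", nms)))
})

test_that("remodeling requires ATP plus Mg2+", {
  r <- rate_set()
  no_mg <- assemble_scheme(r, assay_condition("ATP", mg = FALSE))
  expect_true(is.na(scheme_rate(no_mg, "remodel_DT")))
  adp <- assemble_scheme(r, assay_condition("ADP"))
  expect_true(is.na(scheme_rate(adp, "remodel_DT")))
  # DNA present with ATP multiplies the remodeling rate
  dna <- assemble_scheme(r, assay_condition("ATP", dna = TRUE))
  expect_equal(scheme_rate(dna, "remodel_DT"), r$k2 * r$k2_dna_factor)
})

test_that("unknown species and malformed conditions are rejected", {
  expect_error(species_state(c(Z = 1)), "unknown species")
  expect_error(species_state(c(D = -1)), ">= 0")
  expect_error(assemble_scheme(rate_set(), condition = list(a = 1)),
               "assay_condition")
})
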