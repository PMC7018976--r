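test_that("far-separated domains carry independent identical beads", {
  pars <- model_parameters()
  cfg <- cfg_unit()
  # 4-um domains, 4-um apart, with a 4-um margin to each clamped end
  two <- nanobead:::reach_two_domain_state(pars, 5e-5, 1, 4000, 4000, cfg)
  beads <- measure_beads(two)
  expect_identical(nrow(beads), 2L)
  expect_identical(count_beads(two), 2L)
  expect_lt(abs(diff(beads$r_b)) / beads$r_b[1], 0.01)
  # each bead matches the single-domain solution
  one <- continuation(seq(0, 5e-5, length.out = 11), function(v)
    list(fields = single_domain_profiles(pars, v, 1, L_domain = 4000),
         params = pars), config = cfg, param_name = "sigma0")
  expect_lt(abs(max(beads$r_b) / one$table$r_b_nm[11] - 1), 0.01)
})

test_that("touching domains produce a single bead", {
  pars <- model_parameters()
  sh <- nanobead:::reach_two_domain_state(pars, 3e-5, 1, 8000, 0,
                                          cfg_unit())
  expect_identical(count_beads(sh), 1L)
})

test_that("the merge criterion check compares against the bead diameter", {
  fake <- structure(list(separations = seq(0, 4000, by = 400),
                         critical_separation = 360,
                         critical_unresolved = FALSE),
                    class = "merge_study_result")
  expect_true(merge_criterion_check(fake, r_b_far = 180))   # exactly 2 r_b
  expect_true(merge_criterion_check(fake, r_b_far = 350))   # within one step
  expect_false(merge_criterion_check(fake, r_b_far = 700))
  fake$critical_unresolved <- TRUE
  expect_identical(merge_criterion_check(fake, 180), NA)
})

test_that("low-density merges are smooth and obey the 2 r_b rule", {
  pars <- model_parameters()
  ms <- merge_study(pars, sigma0 = 3e-5, kappa_ratio = 1, L_domain = 8000,
                    separations = seq(0, 4000, length.out = 11),
                    direction = "both", config = cfg_unit())
  expect_identical(ms$transition_type, "smooth")
  expect_identical(ms$hysteresis_width, 0)
  tab <- ms$decreasing
  expect_true(all(tab$n_beads[tab$separation_nm > 400] == 2L,
                  na.rm = TRUE))
  expect_identical(tab$n_beads[tab$separation_nm == 0], 1L)
  rb_far <- tab$r_b_nm[tab$separation_nm == 4000]
  expect_true(isTRUE(merge_criterion_check(ms, rb_far)))
})

test_that("stiff-domain merging is hysteretic with an energy gap", {
  ms <- t3_study()
  expect_identical(ms$transition_type, "snap_through")
  expect_gt(ms$hysteresis_width, 0)
  expect_gt(ms$energy_gap, 0)
  expect_false(ms$critical_unresolved)
  # the quasi-static two-bead branch disappears between 1 and 1.6 um
  expect_gte(ms$critical_separation, 1000)
  expect_lte(ms$critical_separation, 1600)
  # metastable one-bead states coexist with two-bead states
  d <- ms$decreasing[order(ms$decreasing$separation_nm), ]
  u <- ms$increasing
  overlap <- !is.na(d$n_beads) & !is.na(u$n_beads) & d$n_beads != u$n_beads
  expect_gt(sum(overlap), 0)
})

test_that("merge studies export a tidy CSV", {
  ms <- t3_study()
  f <- withr::local_tempfile(fileext = ".csv")
  write_merge_study_csv(ms, f)
  d <- utils::read.csv(f)
  expect_identical(names(d), c("separation_nm", "n_beads", "r_b_nm",
                               "energy_pNnm", "direction"))
  expect_setequal(unique(d$direction), c("decreasing", "increasing"))
})
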