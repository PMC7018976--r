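test_that("bare-tube energy matches the closed form kappa H^2 x area", {
  pars <- model_parameters()
  Req <- equilibrium_tube_radius(320, 0.064)
  uni <- solve_shape(homogeneous_profiles(pars), pars,
                     config = solver_config(mesh_size = 401,
                                            edge_radius = Req))
  e <- total_energy(uni)
  closed <- pars$kappa / (4 * Req^2) * 2 * pi * pars$Rc * pars$Lc
  expect_equal(e$bending, closed, tolerance = 1e-6)
  expect_equal(e$total, e$bending + e$gaussian + e$aggregation +
                 e$gradient + e$entropic)
  expect_equal(e$aggregation, 0)
  expect_equal(e$gradient, 0)
  expect_equal(e$entropic, 0)
})

test_that("plateau protein on a fixed shape moves only bending and aggregation", {
  pars <- model_parameters()
  tube <- homog_tube()
  e0 <- total_energy(tube, homogeneous_profiles(pars), pars)
  # same geometry, protein added (sigma' = 0 away from the shoulders)
  e1 <- total_energy(tube, single_domain_profiles(pars, 5e-5, 1), pars)
  expect_equal(e1$gaussian, e0$gaussian)
  expect_equal(e1$gradient, e0$gradient)   # beta = 0
  expect_lt(e1$aggregation, e0$aggregation)
  expect_gt(e1$bending, e0$bending)        # (H - C)^2 grows for C < 0
})

test_that("energy is invariant under axial translation", {
  tube <- homog_tube()
  shifted <- tube
  shifted$z <- shifted$z + 5000
  expect_equal(total_energy(shifted)$total, total_energy(tube)$total)
})

test_that("the entropic term is negligible against bending", {
  br <- fig3_branch()
  sh <- br$shapes[[26]]
  pe <- model_parameters(include_entropy = TRUE)
  e <- total_energy(sh, single_domain_profiles(pe, 1.25e-4, 1), pe)
  expect_lt(abs(e$entropic) / e$bending, 0.01)
})

test_that("heterogeneity raises the energy density of the undeformed tube", {
  # the driving force for bead formation: at the bare-tube curvature the
  # local density exceeds W0 for any tabulated density or rigidity contrast
  pars <- model_parameters()
  H0 <- 1 / (2 * pars$Rc)
  W0 <- pars$kappa * H0^2
  for (sig in c(1e-5, 5e-5, 1.25e-4, 3.75e-4)) {
    for (kr in c(1, 2, 11, 30)) {
      W <- bending_energy_density(H0, 0, sig, kr * pars$kappa,
                                  -0.9 * pars$kappa, pars) +
        protein_energy_density(sig, 0, pars)
      expect_gt(W, W0 - 1e-12)
    }
  }
})

test_that("quadrature error falls below 0.1 percent under mesh doubling", {
  pars <- model_parameters()
  tot <- vapply(c(601, 1201), function(m) {
    br <- continuation(seq(0, 2e-5, length.out = 5), function(v)
      list(fields = single_domain_profiles(pars, v, 1), params = pars),
      config = solver_config(mesh_size = m), param_name = "sigma0")
    br$table$energy_pNnm[5]
  }, numeric(1))
  expect_lt(abs(tot[2] / tot[1] - 1), 1e-3)
})

test_that("mismatched field and shape grids are rejected", {
  pars <- model_parameters()
  tube <- homog_tube()
  short <- model_parameters(Lc = 5000)
  expect_error(total_energy(tube, homogeneous_profiles(short), pars),
               "not covered")
})
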