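pars <- model_parameters()

test_that("spontaneous curvature is linear in density with the cone sign", {
  expect_equal(spontaneous_curvature(0, pars), 0)
  expect_equal(spontaneous_curvature(1.25e-4, pars), -0.025)
  expect_equal(spontaneous_curvature(2.5e-5, pars), -5e-3)
  expect_error(spontaneous_curvature(-1e-5, pars), "non-negative")
})

test_that("protein energy density reproduces hand-computed values", {
  expect_equal(protein_energy_density(0, 0, pars), 0)
  expect_equal(protein_energy_density(2.5e-5, 0, pars), -8e-3)
  # beta = 0 kills the gradient term
  expect_equal(protein_energy_density(2.5e-5, 1e-8, pars), -8e-3)
  pb <- model_parameters(beta = 3.2e11)
  expect_equal(protein_energy_density(2.5e-5, 1e-8, pb),
               -8e-3 + 3.2e11 * 1e-16)
  # entropic term: sigma -> 0 limit is 0, not an error
  pe <- model_parameters(include_entropy = TRUE)
  expect_equal(protein_energy_density(0, 0, pe), 0)
  expect_lt(protein_energy_density(1e-5, 0, pe),
            protein_energy_density(1e-5, 0, pars))
})

test_that("bending energy density follows the heterogeneous Helfrich form", {
  H0 <- 1 / 70
  expect_equal(bending_energy_density(H0, 0, 0, 320, -288, pars), 320 / 4900)
  # curvature equal to the spontaneous curvature costs nothing
  C <- spontaneous_curvature(1e-4, pars)
  expect_equal(bending_energy_density(C, 0, 1e-4, 320, -288, pars), 0)
  # flat (K = 0) surfaces are insensitive to the Gaussian modulus
  expect_equal(bending_energy_density(H0, 0, 0, 320, -1e4, pars),
               bending_energy_density(H0, 0, 0, 320, 1e4, pars))
  expect_error(bending_energy_density(H0, 0, 0, -1, 0, pars), "positive")
})

test_that("limit mean curvature and its linearization match hand values", {
  expect_equal(mean_curvature_center(0, 1, pars), 1 / 70)
  expect_equal(mean_curvature_center(2.5e-5, 1, pars),
               -5e-3 + sqrt(1 / 4900 + 2.5e-5), tolerance = 1e-10)
  expect_equal(mean_curvature_center(2.5e-5, 1, pars), 0.0101354,
               tolerance = 1e-4)
  expect_equal(mean_curvature_center_linearized(2.5e-5, 1, pars),
               -5e-3 + 1 / 70 + (35 / 320) * 8e-3, tolerance = 1e-10)
  expect_equal(mean_curvature_center_linearized(0, 4, pars), 1 / 140)
  # huge gradient penalty drives the radicand negative
  pb <- model_parameters(beta = 1e20)
  expect_error(mean_curvature_center(1e-4, 1, pb, grad_sigma = 1e-7),
               "radicand")
})

test_that("linearization error vanishes at higher order in the density", {
  sig <- 2.5e-5 * 2^-(0:3)
  err <- abs(mean_curvature_center_linearized(sig, 1, pars) -
               mean_curvature_center(sig, 1, pars))
  expect_lt(err[1] / mean_curvature_center(sig[1], 1, pars), 0.01)
  # the Taylor remainder of sqrt(H0^2 + alpha sigma^2/kappa) is O(sigma^4):
  # halving sigma shrinks the gap sixteen-fold
  ratio <- err[-length(err)] / err[-1]
  expect_true(all(ratio > 12 & ratio < 20))
})

test_that("limit curvature decreases in density and rigidity ratio", {
  sig <- seq(0, 2.5e-4, length.out = 40)
  H <- mean_curvature_center(sig, 1, pars)
  expect_true(all(diff(H) < 0))
  kr <- seq(1, 30, length.out = 40)
  Hk <- mean_curvature_center(2.5e-5, 1, pars)
  Hks <- vapply(kr, function(k) mean_curvature_center(2.5e-5, k, pars),
                numeric(1))
  expect_true(all(diff(Hks) < 0))
  expect_equal(Hks[1], Hk)
  # kappa_ratio -> infinity leaves only the spontaneous curvature
  expect_equal(mean_curvature_center(2.5e-5, 1e12, pars), -5e-3,
               tolerance = 1e-5)
})

test_that("the zero-curvature locus satisfies its closed form", {
  # on the locus, (mu phi sigma)^2 kappa_ratio = 1/(2Rc)^2 + alpha sigma^2/kappa
  sig <- c(5e-5, 1e-4, 2e-4)
  kr_zero <- (1 / 4900 + pars$alpha * sig^2 / pars$kappa) /
    (pars$mu * pars$phi * sig)^2
  for (i in seq_along(sig))
    expect_equal(mean_curvature_center(sig[i], kr_zero[i], pars), 0,
                 tolerance = 1e-12)
})

test_that("analytic bead radii reproduce hand values and guard their domain", {
  expect_equal(bead_radius_analytic(0, 1, pars), 35)
  expect_equal(bead_radius_analytic(2.5e-5, 1, pars), 49.33,
               tolerance = 1e-3)
  expect_equal(bead_radius_linearized(0, 1, pars), 35)
  expect_equal(bead_radius_linearized(0, 4, pars), 70)
  expect_equal(bead_radius_linearized(2.5e-5, 1, pars),
               35 * (1 + 0.35 - 0.06125), tolerance = 1e-10)
  # past the zero-curvature locus the cylindrical approximation fails
  expect_error(bead_radius_analytic(2e-4, 25, pars), "sign")
})

test_that("equilibrium tube radius follows the tether closed form", {
  expect_equal(equilibrium_tube_radius(320, 0.064), 35.3553, tolerance = 1e-5)
  expect_equal(equilibrium_tube_radius(320, 0.064), 35, tolerance = 0.02)
  expect_equal(equilibrium_tube_radius(9600, 0.064), 193.65, tolerance = 1e-4)
  expect_equal(equilibrium_tube_radius(320, 4 * 0.064),
               equilibrium_tube_radius(320, 0.064) / 2)
  expect_error(equilibrium_tube_radius(320, 0), "positive")
})

test_that("induced length scales and their log ratio behave as defined", {
  ls <- induced_length_scales(1.25e-4, 0.064, 320, pars)
  expect_equal(ls$l_sigma, 40)
  expect_equal(ls$l_kappa, 35.3553, tolerance = 1e-5)
  expect_equal(ls$log_ratio, log10(40 / ls$l_kappa))
  # positive length also for negative phi (magnitude convention)
  expect_gt(induced_length_scales(1e-4, 0.064, 320,
                                  model_parameters(phi = -0.5))$l_sigma, 0)
  z <- induced_length_scales(0, 0.064, 320, pars)
  expect_identical(z$l_sigma, Inf)
  expect_identical(z$log_ratio, Inf)
  expect_error(induced_length_scales(1e-4, 0, 320, pars), "positive")
})
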