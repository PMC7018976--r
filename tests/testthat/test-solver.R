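test_that("the uniform cylinder is an exact fixed point of the ODE system", {
  pars <- model_parameters()
  R <- equilibrium_tube_radius(pars$kappa, pars$lambda0)
  fields <- homogeneous_profiles(pars, n_grid = 101)
  st <- c(r = R, z = 0, psi = pi / 2, H = 1 / (2 * R), flux = 0,
          lam = pars$lambda0)
  d <- ode_rhs(st, 1e4, fields, pars)
  expect_equal(unname(d[c("r", "psi", "H", "flux", "lam")]),
               rep(0, 5), tolerance = 1e-14)
  expect_equal(unname(d["z"]), 1)
  # constant density on uniform rigidity: no tension gradient
  ps <- single_domain_profiles(pars, 1e-4, 1)
  stc <- c(r = R, z = 0, psi = pi / 2, H = 1 / (2 * R), flux = 0,
           lam = pars$lambda0)
  expect_equal(unname(ode_rhs(stc, 1e4, ps, pars)["lam"]), 0,
               tolerance = 1e-20)  # domain centre: sigma' = 0
  expect_error(ode_rhs(c(r = -1, z = 0, psi = pi / 2, H = 0, flux = 0,
                         lam = 0), 0, fields, pars), "singular")
})

test_that("an injected sign error in the moment flux breaks the fixed point", {
  pars <- model_parameters()
  good <- nanobead:::cylinder_oracle_residual(pars)
  expect_lt(good, 1e-12)
  broken_rhs <- function(state, s, fields, params) {
    d <- ode_rhs(state, s, fields, params)
    # flip the tension contribution to the normal balance
    d["flux"] <- d["flux"] - 2 * state["r"] * 2 * state["lam"] * state["H"]
    d
  }
  expect_gt(nanobead:::cylinder_oracle_residual(pars, rhs_fun = broken_rhs),
            1e-2)
})

test_that("boundary residuals vanish at equilibrium and flag mismatches", {
  pars <- model_parameters(lambda0 = 320 / 4900)  # tension matching r = Rc
  edge <- c(r = 35, z = 0, psi = pi / 2, H = 1 / 70, flux = 0,
            lam = pars$lambda0)
  res <- boundary_residuals(edge, edge, pars, mode = "full")
  expect_equal(unname(res), rep(0, 6))
  pert <- edge; pert["r"] <- 36
  expect_equal(unname(boundary_residuals(pert, edge, pars, "full"))[1], 1)
  mis <- edge; mis["lam"] <- pars$lambda0 + 0.01
  res2 <- boundary_residuals(edge, mis, pars, "full")
  expect_equal(unname(res2[1:5]), rep(0, 5))
  expect_equal(unname(res2[6]), 0.01)
})

test_that("the homogeneous solve reproduces the tether radius", {
  pars <- model_parameters()
  tube <- homog_tube()
  mid <- which.min(abs(tube$u - pars$Lc / 2))
  expect_equal(tube$r[mid], equilibrium_tube_radius(320, 0.064),
               tolerance = 5e-3)
  cons <- shape_consistency(tube)
  expect_lt(max(cons), 1e-6)
  # clamped exactly at the natural radius the solution is a uniform cylinder
  Req <- equilibrium_tube_radius(320, 0.064)
  uni <- solve_shape(homogeneous_profiles(pars), pars,
                     config = solver_config(mesh_size = 401,
                                            edge_radius = Req))
  expect_lt(max(abs(uni$r - Req)) / Req, 1e-8)
  expect_lt(max(abs(uni$lam - pars$lambda0)), 1e-10)
})

test_that("interior radius tracks 0.5*sqrt(kappa/lambda) across tensions", {
  pars <- model_parameters()
  lam_path <- c(0.064, 0.032, 0.016)
  br <- continuation(lam_path, function(v) {
    p <- do.call(model_parameters,
                 utils::modifyList(unclass(pars), list(lambda0 = v)))
    list(fields = homogeneous_profiles(p), params = p)
  }, config = solver_config(mesh_size = 601), param_name = "lambda0")
  for (i in seq_along(lam_path)) {
    sh <- br$shapes[[i]]
    mid <- which.min(abs(sh$u - pars$Lc / 2))
    expect_equal(sh$r[mid],
                 equilibrium_tube_radius(pars$kappa, lam_path[i]),
                 tolerance = 5e-3)
  }
})

test_that("full-domain solves of centred profiles are mirror symmetric", {
  pars <- model_parameters()
  br <- continuation(c(0, 1e-5, 2e-5), function(v)
    list(fields = single_domain_profiles(pars, v, 1), params = pars),
    config = solver_config(mesh_size = 601, symmetry_mode = "full"),
    param_name = "sigma0")
  sh <- br$shapes[[3]]
  expect_lt(max(abs(sh$r - rev(sh$r))), 1e-3 * pars$Rc)
  # half- and full-domain routes agree
  half <- continuation(c(0, 1e-5, 2e-5), function(v)
    list(fields = single_domain_profiles(pars, v, 1), params = pars),
    config = solver_config(mesh_size = 601, symmetry_mode = "half"),
    param_name = "sigma0")$shapes[[3]]
  expect_equal(max(sh$r), max(half$r), tolerance = 1e-4)
  # half-domain mode refuses asymmetric inputs
  off <- make_off_center_profiles(pars)
  expect_error(solve_shape(off, pars,
                           config = solver_config(mesh_size = 401,
                                                  symmetry_mode = "half")),
               "symmetric")
})

test_that("solved bead radius matches the cylindrical-bead limit at low density", {
  pars <- model_parameters()
  br <- small_branch()
  for (i in c(3, 4, 5)) {   # sigma0 = 1, 1.5, 2 x 1e-5
    s0 <- br$values[i]
    expect_equal(br$table$r_b_nm[i], bead_radius_analytic(s0, 1, pars),
                 tolerance = 0.10)
  }
})

test_that("solved tension field equals the line integral of its gradient", {
  pars <- model_parameters()
  sh <- small_branch()$shapes[[6]]
  n <- length(sh$u)
  d <- function(v) {
    out <- numeric(n)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (sh$u[3:n] - sh$u[1:(n - 2)])
    out[1] <- out[2]; out[n] <- out[n - 1]
    out
  }
  # tension gradient recomputed a posteriori from the solved fields
  w <- sh$r / pars$Rc
  dsg_ds <- w * sh$dsigma_du
  C <- pars$mu * pars$phi * sh$sigma
  lamp_s <- 2 * (sh$kappa * pars$mu * pars$phi * (sh$H - C) +
                   pars$alpha * sh$sigma) * dsg_ds -
    w * d(sh$kappa) * (sh$H - C)^2 - w * d(sh$kappaG) * sh$K
  steps <- rev((lamp_s[-1] + lamp_s[-n]) / 2 * diff(sh$s))
  lam_rec <- rev(pars$lambda0 - cumsum(c(0, steps)))
  expect_lt(max(abs(lam_rec - sh$lam)) / pars$lambda0, 1e-3)
})

test_that("converged shapes extremize the energy; perturbed shapes do not", {
  br <- small_branch()
  bead <- br$shapes[[6]]
  expect_lt(as.numeric(verify_stationarity(bead)), 1e-4)
  Req <- equilibrium_tube_radius(320, 0.064)
  pars <- model_parameters()
  uni <- solve_shape(homogeneous_profiles(pars), pars,
                     config = solver_config(mesh_size = 401,
                                            edge_radius = Req))
  expect_lt(as.numeric(verify_stationarity(uni)), 1e-6)
  expect_lt(shape_equation_residual(bead), 1e-2)
  # test of the test: a perturbed configuration fails the oracle
  fake <- bead
  fake$r <- fake$r * (1 + 0.05 * exp(-((fake$s - mean(fake$s)) / 2000)^2))
  expect_gt(as.numeric(verify_stationarity(fake)), 1e-4)
})

test_that("the axial force is mode-independent at equilibrium", {
  bead <- small_branch()$shapes[[6]]
  spread <- verify_axial_balance(bead)
  expect_lt(as.numeric(spread), 1e-3)
  # the tether force drops below the bare-tube value as the bead grows
  Fz <- attr(spread, "F_axial")
  expect_lt(Fz, 2 * pi * sqrt(2 * 320 * 0.064))
  expect_gt(Fz, 0)
  fake <- bead
  fake$r <- fake$r * (1 + 0.08 * exp(-((fake$u - 8000) / 1500)^2))
  expect_gt(as.numeric(verify_axial_balance(fake)), 1e-2)
})

test_that("bead radius is mesh converged", {
  pars <- model_parameters()
  rb <- vapply(c(401, 801), function(m) {
    br <- continuation(seq(0, 2e-5, length.out = 5), function(v)
      list(fields = single_domain_profiles(pars, v, 1), params = pars),
      config = solver_config(mesh_size = m), param_name = "sigma0")
    br$table$r_b_nm[5]
  }, numeric(1))
  expect_lt(abs(rb[2] / rb[1] - 1), 0.002)
})

test_that("bead radius is insensitive to the tanh transition width", {
  pars <- model_parameters()
  rb <- vapply(c(175, 700), function(w) {
    br <- continuation(seq(0, 2e-5, length.out = 5), function(v)
      list(fields = single_domain_profiles(pars, v, 1,
                                           transition_width = w),
           params = pars),
      config = solver_config(mesh_size = 401), param_name = "sigma0")
    br$table$r_b_nm[5]
  }, numeric(1))
  expect_lt(abs(rb[2] / rb[1] - 1), 0.02)
})

test_that("continuation seeds, bisects, and truncates as specified", {
  pars <- model_parameters()
  cfg <- solver_config(mesh_size = 401, step_halving_limit = 3)
  one <- continuation(1e-5, function(v)
    list(fields = single_domain_profiles(pars, v, 1), params = pars),
    config = cfg, param_name = "sigma0")
  direct <- solve_shape(single_domain_profiles(pars, 1e-5, 1), pars,
                        config = cfg)
  expect_equal(one$shapes[[1]]$r, direct$r)
  # an unreachable value truncates the branch without raising
  br <- continuation(c(1e-5, 5e-3), function(v)
    list(fields = single_domain_profiles(pars, v, 1), params = pars),
    config = cfg, param_name = "sigma0")
  expect_true(br$converged[1])
  expect_false(br$converged[2])
  expect_identical(br$truncated_at, 2L)
})
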