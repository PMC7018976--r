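test_that("tanh fields hit their plateau and baseline to 0.1 percent", {
  s <- seq(0, 2e4, length.out = 4001)
  dom <- domain_spec(center = 1e4, length = 8000, amplitude = 1.25e-4,
                     transition_width = 350)
  f <- tanh_profile(s, list(dom), baseline = 0)
  expect_equal(f[s == 1e4], 1.25e-4, tolerance = 1e-3)
  expect_lt(max(abs(f[s <= 6000 - 5 * 350])), 1e-3 * 1.25e-4)
  expect_equal(tanh_profile(s, list(), baseline = 7), rep(7, length(s)))
  # amplitude equal to baseline is a no-op
  dom2 <- domain_spec(1e4, 8000, 5, 350)
  expect_equal(tanh_profile(s, list(dom2), baseline = 5), rep(5, length(s)),
               tolerance = 1e-12)
})

test_that("profile derivatives are analytic and scale as 1/w^2", {
  s <- seq(0, 2e4, length.out = 8001)
  h <- s[2] - s[1]
  for (w in c(200, 400, 800)) {
    dom <- list(domain_spec(1e4, 8000, 1, w))
    f <- tanh_profile(s, dom, 0)
    d1 <- tanh_profile(s, dom, 0, deriv = 1)
    d2 <- tanh_profile(s, dom, 0, deriv = 2)
    # analytic first derivative matches central differences within the
    # O(h^2 f''') truncation error of the difference itself
    fd <- (f[3:8001] - f[1:7999]) / (2 * h)
    expect_lt(max(abs(fd - d1[2:8000])), h^2 / w^3)
    # curvature of the transition scales like 1/w^2
    # peak of tanh(u) sech(u)^2 is 2/(3 sqrt(3))
    expect_equal(max(abs(d2)) * w^2, 2 / (3 * sqrt(3)), tolerance = 0.01)
  }
})

test_that("single-domain profiles are mirror symmetric and well-formed", {
  pars <- model_parameters()
  ps <- single_domain_profiles(pars, 1.25e-4, kappa_ratio = 11,
                               delta_kappaG = 0.5)
  expect_s3_class(ps, "profile_set")
  expect_true(all(ps$sigma >= 0))
  expect_true(all(ps$kappa >= pars$kappa))
  expect_equal(max(ps$kappa), 11 * pars$kappa, tolerance = 1e-3)
  expect_equal(max(ps$kappaG) / min(ps$kappaG), 1 / 1.5, tolerance = 1e-3)
  sgrid <- seq(0, pars$Lc, length.out = 997)
  expect_equal(ps$funs$sigma(sgrid), ps$funs$sigma(pars$Lc - sgrid))
  expect_error(single_domain_profiles(pars, 1e-4, L_domain = 3e4), "Lc")
  expect_error(single_domain_profiles(pars, -1e-5), "non-negative")
})

test_that("touching two-domain profiles equal one double-length domain", {
  pars <- model_parameters()
  two <- two_domain_profiles(pars, 1e-4, L_domain = 8000, L_separation = 0)
  one <- single_domain_profiles(pars, 1e-4, L_domain = 16000,
                                transition_width =
                                  two$domain_meta[[1]]$transition_width)
  expect_equal(two$sigma, one$sigma, tolerance = 1e-12)
  # far domains sit where the geometry says
  far <- two_domain_profiles(pars, 1e-4, L_domain = 8000,
                             L_separation = 4000)
  expect_equal(far$domain_meta[[1]]$center, 4000)
  expect_equal(far$domain_meta[[2]]$center, 16000)
  expect_error(two_domain_profiles(pars, 1e-4, L_domain = 8000,
                                   L_separation = 6000), "exceeds")
})

test_that("overlapping domains with different amplitudes are rejected", {
  s <- seq(0, 2e4, length.out = 101)
  d1 <- domain_spec(9000, 6000, 1, 200)
  d2 <- domain_spec(11000, 6000, 2, 200)
  expect_error(tanh_profile(s, list(d1, d2), 0), "ambiguous")
  # identical amplitudes overlap via pointwise max: plateau is preserved
  d2b <- domain_spec(11000, 6000, 1, 200)
  f <- tanh_profile(s, list(d1, d2b), 0)
  expect_lt(max(f), 1 + 1e-6)
  expect_equal(max(f), 1, tolerance = 1e-3)
})

test_that("profile CSV round trip preserves fields and derivatives", {
  pars <- model_parameters()
  ps <- single_domain_profiles(pars, 1e-4, kappa_ratio = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(ps, f)
  back <- read_profiles_csv(f)
  expect_equal(back$sigma, ps$sigma, tolerance = 1e-10)
  expect_equal(back$kappa, ps$kappa, tolerance = 1e-10)
  mid <- seq(1000, 19000, by = 37)
  expect_lt(max(abs(back$funs$sigma(mid) - ps$funs$sigma(mid))),
            1e-4 * max(ps$sigma))
  expect_lt(max(abs(back$funs$dsigma(mid) - ps$funs$dsigma(mid))),
            1e-2 * max(abs(ps$funs$dsigma(mid))))
})
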