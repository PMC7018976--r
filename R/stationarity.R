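# Discrete energy of a perturbed generating curve, with the material
# fields (sigma, kappa, kappa_G, lambda) pinned to the unperturbed
# parameter. Curvatures are recomputed from the perturbed curve by central
# differences, so this evaluation is independent of the solver's ODE
# algebra.
curve_energy <- function(t, r, z, kap, kG, Cs, wprot, lam) {
  n <- length(t)
  d <- function(v) {
    out <- numeric(n)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    out[1] <- (v[2] - v[1]) / (t[2] - t[1])
    out[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
    out
  }
  rp <- d(r); zp <- d(z)
  Jac <- sqrt(rp^2 + zp^2)          # ds/dt of the perturbed curve
  psi <- atan2(zp, rp)
  psip <- d(psi) / Jac
  H <- (psip + sin(psi) / r) / 2
  K <- psip * sin(psi) / r
  dens <- kap * (H - Cs)^2 + kG * K + wprot + lam
  trapz(t, dens * 2 * pi * r * Jac)
}

#' First-variation (stationarity) check of a solved shape
#'
#' Verifies that a converged shape extremizes the membrane energy: the
#' shape is displaced along its normal by a set of smooth, compactly
#' supported bumps of amplitude eps (in units of Rc), the total energy
#' (curvature-elastic + protein + tension-weighted area) is re-evaluated
#' from the perturbed generating curve by finite differences -- a route
#' independent of the solver's ODE reduction -- and the centred derivative
#' dE/d(eps) is formed. At an equilibrium it vanishes to O(eps^2), so the
#' returned norm (max |dE/d eps| over the bumps, divided by the bending
#' energy) is small; for a non-equilibrium shape it is O(1).
#'
#' The fields (sigma, kappa, kappa_G, lambda) ride with the unperturbed
#' parameterization under the virtual displacement, which is the normal
#' variation that generates the shape equation. The gradient penalty is
#' evaluated on the unperturbed metric; with the default beta = 0 this is
#' exact.
#'
#' @param shape A \code{membrane_shape}.
#' @param fields A \code{profile_set} (defaults to the fields sampled in
#'   the shape).
#' @param params A [model_parameters()] object (defaults to the shape's).
#' @param eps Perturbation amplitude in units of Rc.
#' @param n_bumps Number of Gaussian bumps spread over the interior.
#' @return The dimensionless first-variation norm (also carries the
#'   per-bump derivatives as attribute \code{"derivatives"}).
#' @export
verify_stationarity <- function(shape, fields = NULL, params = NULL,
                                eps = 1e-3, n_bumps = 5) {
  stopifnot(inherits(shape, "membrane_shape"))
  if (is.null(params)) params <- shape$params
  t <- shape$s                      # deformed arclength parameter
  if (is.null(fields)) {
    sg <- shape$sigma; dsg_du <- shape$dsigma_du
    kap <- shape$kappa; kG <- shape$kappaG
  } else {
    sg <- fields$funs$sigma(shape$u); dsg_du <- fields$funs$dsigma(shape$u)
    kap <- fields$funs$kappa(shape$u); kG <- fields$funs$kappaG(shape$u)
  }
  dsg_ds <- (shape$r / params$Rc) * dsg_du
  Cs <- params$mu * params$phi * sg
  wprot <- protein_energy_density(sg, dsg_ds, params)
  L <- max(t) - min(t)
  centers <- min(t) + L * seq(0.2, 0.8, length.out = n_bumps)
  width <- L / 30
  nx <- sin(shape$psi); nz <- -cos(shape$psi)   # outward normal
  Eb <- total_energy(shape, fields, params)$bending
  derivs <- vapply(centers, function(ck) {
    phi <- exp(-(t - ck)^2 / (2 * width^2))
    phi[abs(t - ck) > 6 * width] <- 0
    amp <- eps * params$Rc
    Ep <- curve_energy(t, shape$r + amp * phi * nx, shape$z + amp * phi * nz,
                       kap, kG, Cs, wprot, shape$lam)
    Em <- curve_energy(t, shape$r - amp * phi * nx, shape$z - amp * phi * nz,
                       kap, kG, Cs, wprot, shape$lam)
    (Ep - Em) / (2 * eps)
  }, numeric(1))
  norm <- max(abs(derivs)) / Eb
  attr(norm, "derivatives") <- derivs
  norm
}

#' Axial-force constancy check of a solved shape
#'
#' Because the membrane is locally area-incompressible, the generating
#' curve r(u) alone determines the whole configuration (the arclength
#' follows from ds = (Rc/r) du and z by quadrature), so the membrane
#' energy E\[r(u)\] is an unconstrained functional of r. An equilibrium
#' tube held by an axial force F extremizes E - F z(S): for every radial
#' perturbation mode the ratio dE/dz(S) must equal one and the same F.
#' This function perturbs r(u) with several independent compact bumps,
#' recomputes E and the axial extent z(S) from scratch by finite
#' differences, and returns the relative spread of dE/dz across modes --
#' near zero at a genuine equilibrium, order one otherwise. Unlike
#' [verify_stationarity()] this oracle does not use the solved tension
#' field at all, so it independently validates the tangential force
#' balance. The axial force itself is attached as attribute
#' \code{"F_axial"} \[pN\].
#'
#' @param shape A \code{membrane_shape}.
#' @param params A [model_parameters()] object (defaults to the shape's).
#' @param eps Perturbation amplitude in units of Rc.
#' @param centers Bump centres as fractions of the tube length.
#' @return Relative spread (max deviation from the median) of the axial
#'   force across perturbation modes.
#' @export
verify_axial_balance <- function(shape, params = NULL, eps = 0.02,
                                 centers = c(0.3, 0.42, 0.58, 0.7)) {
  stopifnot(inherits(shape, "membrane_shape"))
  if (is.null(params)) params <- shape$params
  Rc <- params$Rc
  u <- shape$u
  n <- length(u)
  sg <- shape$sigma
  C <- params$mu * params$phi * sg
  kap <- shape$kappa; kG <- shape$kappaG
  wagg <- -params$alpha * sg^2
  d <- function(v) {
    out <- numeric(n)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (u[3:n] - u[1:(n - 2)])
    out[1] <- (v[2] - v[1]) / (u[2] - u[1])
    out[n] <- (v[n] - v[n - 1]) / (u[n] - u[n - 1])
    out
  }
  E_and_z <- function(r) {
    ru <- d(r)
    cospsi <- pmin(1, pmax(-1, (r / Rc) * ru))
    sinpsi <- sqrt(pmax(0, 1 - cospsi^2))
    psi <- atan2(sinpsi, cospsi)
    psis <- (r / Rc) * d(psi)
    H <- (psis + sinpsi / r) / 2
    K <- psis * sinpsi / r
    dens <- kap * (H - C)^2 + kG * K + wagg
    c(E = trapz(u, dens) * 2 * pi * Rc,
      z = trapz(u, sinpsi * Rc / r))
  }
  L <- max(u) - min(u)
  width <- L / 40
  res <- vapply(centers, function(fr) {
    ck <- min(u) + fr * L
    phi <- exp(-((u - ck) / width)^2)
    p <- E_and_z(shape$r + eps * Rc * phi)
    m <- E_and_z(shape$r - eps * Rc * phi)
    (p["E"] - m["E"]) / (p["z"] - m["z"])
  }, numeric(1))
  F0 <- stats::median(res)
  out <- max(abs(res - F0)) / abs(F0)
  attr(out, "F_axial") <- F0
  out
}

#' Pointwise residual of the normal force balance
#'
#' Recomputes the shape-equation residual from a solved shape by direct
#' finite differencing of the bending moment (surface Laplacian of
#' kappa (H - C)) in the deformed arclength, rather than through the
#' solver's auxiliary flux variable. Returns the root-mean-square residual
#' over the interior, scaled by kappa/Rc^3 (the natural magnitude of the
#' individual terms). This is a consistency diagnostic;
#' [verify_stationarity()] is the energy-based oracle.
#'
#' @param shape A \code{membrane_shape}.
#' @param params A [model_parameters()] object (defaults to the shape's).
#' @param trim Fraction of nodes dropped at each end before taking the RMS.
#' @return Scaled RMS residual (dimensionless).
#' @export
shape_equation_residual <- function(shape, params = NULL, trim = 0.02) {
  stopifnot(inherits(shape, "membrane_shape"))
  if (is.null(params)) params <- shape$params
  s <- shape$s
  sg <- shape$sigma
  dsg <- (shape$r / params$Rc) * shape$dsigma_du
  kap <- shape$kappa; kG <- shape$kappaG
  n <- length(s)
  d <- function(v) {
    out <- numeric(n)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
    out[1] <- out[2]; out[n] <- out[n - 1]
    out
  }
  kGp <- d(kG)
  C <- params$mu * params$phi * sg
  M <- kap * (shape$H - C)
  lapM <- d(shape$r * d(M)) / shape$r
  Gcov <- d(kGp * sin(shape$psi)) / shape$r
  H <- shape$H; K <- shape$K
  res <- lapM - Gcov - 2 * kap * H * (H - C)^2 +
    2 * kap * (H - C) * (2 * H^2 - K) +
    2 * H * params$alpha * sg^2 - 2 * H * params$beta * dsg^2 -
    params$p - 2 * shape$lam * H
  keep <- seq(max(2L, ceiling(n * trim)), min(n - 1L, floor(n * (1 - trim))))
  sqrt(mean(res[keep]^2)) / (params$kappa / params$Rc^3)
}
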