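#' Solver configuration
#'
#' @param mesh_size Number of collocation nodes (>= 200). The default 1001
#'   resolves the tube radius with roughly three points per Rc on a half
#'   tube and the tanh transitions with ~35 points per shoulder.
#' @param tolerance Convergence tolerance on the scaled collocation residual
#'   (max-norm of the midpoint-scheme defect divided by the step). Must be
#'   <= 1e-6; default 1e-9.
#' @param max_iter Maximum Newton iterations per solve.
#' @param symmetry_mode \code{"auto"}, \code{"half"} or \code{"full"}.
#'   Half-domain mode exploits mirror symmetry of centred profiles and
#'   solves on \[Lc/2, Lc\] with symmetry conditions at the midpoint; the
#'   returned shape is always the full tube.
#' @param edge_radius Radius clamped at the tube edge \[nm\]; default the
#'   nominal tube radius Rc. The ~1 percent mismatch with the unloaded
#'   equilibrium radius at the default tension is absorbed by a boundary
#'   layer.
#' @param step_halving_limit Maximum recursive bisections of a continuation
#'   step before the branch is truncated.
#' @return An object of class \code{"solver_config"}.
#' @export
solver_config <- function(mesh_size = 1001, tolerance = 1e-9, max_iter = 30,
                          symmetry_mode = c("auto", "half", "full"),
                          edge_radius = NULL, step_halving_limit = 8) {
  symmetry_mode <- match.arg(symmetry_mode)
  if (mesh_size < 200) stop("mesh_size must be at least 200")
  if (tolerance > 1e-6) stop("tolerance must be <= 1e-6")
  structure(list(mesh_size = as.integer(mesh_size), tolerance = tolerance,
                 max_iter = as.integer(max_iter),
                 symmetry_mode = symmetry_mode, edge_radius = edge_radius,
                 step_halving_limit = as.integer(step_halving_limit)),
            class = "solver_config")
}

# state component order used throughout
STATE_VARS <- c("r", "z", "psi", "H", "flux", "lam")

# scale factors taking physical (nm, pN) state to the dimensionless system
# (lengths in Rc, moduli in kappa, tension in kappa/Rc^2)
state_scale <- function(params) {
  c(r = 1 / params$Rc, z = 1 / params$Rc, psi = 1,
    H = params$Rc, flux = params$Rc / params$kappa,
    lam = params$Rc^2 / params$kappa)
}

# Dimensionless field evaluators. The profiles are material fields: they
# are functions of the reference (area) coordinate u, with s = offset + u.
# t below is u in units of Rc.
scaled_fields <- function(fields, params, offset = 0) {
  Rc <- params$Rc; k0 <- params$kappa
  fn <- fields$funs
  mp <- params$mu * params$phi
  al <- params$alpha; be <- params$beta
  list(
    eval = function(t) {
      u <- offset + t * Rc
      sg <- fn$sigma(u); dsg <- fn$dsigma(u)
      list(
        kap  = fn$kappa(u) / k0,
        kapu = fn$dkappa(u) * Rc / k0,
        Ct   = mp * sg * Rc,
        Ctu  = mp * dsg * Rc^2,
        A    = al * sg^2 * Rc^2 / k0,
        Au   = 2 * al * sg * dsg * Rc^3 / k0,
        bet1 = be * dsg^2 * Rc^2 / k0,
        bet2 = be * dsg * fn$d2sigma(u) * Rc^3 / k0,
        kGu  = fn$dkappaG(u) * Rc / k0,
        kGuu = fn$d2kappaG(u) * Rc^2 / k0
      )
    },
    ptil = params$p * Rc^3 / k0,
    lam0til = params$lambda0 * Rc^2 / k0
  )
}

# Vectorized dimensionless right-hand side in the material coordinate u.
# Local area incompressibility ties the deformed arclength to u through
# ds/du = 1/r (in Rc units), so every arclength derivative of the
# deformed-configuration system picks up a 1/r transport factor while the
# material fields differentiate directly in u. Y is 6 x m (STATE_VARS).
rhs_material <- function(Y, fv, ptil) {
  r <- Y[1L, ]; psi <- Y[3L, ]; H <- Y[4L, ]; f <- Y[5L, ]; lam <- Y[6L, ]
  sp <- sin(psi); cp <- cos(psi)
  spr <- sp / r
  psip_s <- 2 * H - spr            # d(psi)/ds
  K <- psip_s * spr
  HmC <- H - fv$Ct
  r_u <- cp / r
  z_u <- sp / r
  psi_u <- psip_s / r
  H_u <- f / (fv$kap * r^2) - fv$kapu * HmC / fv$kap + fv$Ctu
  Gu <- r_u * fv$kGu * sp + r * fv$kGuu * sp + fv$kGu * cp * psip_s
  flux_u <- ptil + 2 * lam * H + 2 * fv$kap * H * HmC^2 -
    2 * fv$kap * HmC * (2 * H^2 - K) -
    2 * H * fv$A + 2 * H * r^2 * fv$bet1 + Gu
  lam_u <- 2 * fv$kap * fv$Ctu * HmC + fv$Au -
    (cp * fv$bet1 + r^2 * fv$bet2) - fv$kapu * HmC^2 - fv$kGu * K
  rbind(r_u, z_u, psi_u, H_u, flux_u, lam_u, deparse.level = 0)
}

#' Right-hand side of the axisymmetric shape and tension equations
#'
#' First-order arclength form of the normal force balance (shape equation)
#' and tangential force balance (tension variation) on a surface of
#' revolution, with the heterogeneity fields read as functions of
#' arclength. The state is (r, z, psi, H, flux, lam) with tangent-angle
#' conventions r' = cos(psi), z' = sin(psi), 2H = psi' + sin(psi)/r,
#' K = psi' sin(psi)/r, and the auxiliary moment flux
#' flux = r d/ds\[kappa (H - C)\]. On a uniform equilibrium cylinder
#' (r = 0.5 sqrt(kappa/lambda), psi = pi/2, H = 1/(2r), flux = 0) every
#' mechanical derivative vanishes; this fixed point is the primary
#' correctness oracle for the algebra. (The collocation solver integrates
#' the equivalent system in the material area coordinate, where the
#' heterogeneity fields live; on the undeformed tube the two coincide.)
#'
#' @param state Named numeric vector (or 6 x m matrix, rows in the order
#'   r, z, psi, H, flux, lam) in physical units \[nm, rad, nm^-1, pN,
#'   pN/nm\].
#' @param s Arclength position(s) \[nm\].
#' @param fields A \code{profile_set}.
#' @param params A [model_parameters()] object.
#' @return Derivatives of the state with respect to arclength, same shape
#'   as \code{state}.
#' @export
ode_rhs <- function(state, s, fields, params) {
  vec_in <- is.null(dim(state))
  Y <- if (vec_in) matrix(state, nrow = 6L) else state
  if (nrow(Y) != 6L) stop("state must have 6 components (r,z,psi,H,flux,lam)")
  if (any(Y[1L, ] <= 0))
    stop("singular state: radial coordinate r must be positive")
  Rc <- params$Rc; k0 <- params$kappa
  fn <- fields$funs
  mp <- params$mu * params$phi
  r <- Y[1L, ]; psi <- Y[3L, ]; H <- Y[4L, ]; f <- Y[5L, ]; lam <- Y[6L, ]
  sg <- fn$sigma(s); dsg <- fn$dsigma(s); d2sg <- fn$d2sigma(s)
  kap <- fn$kappa(s); kapp <- fn$dkappa(s)
  kGp <- fn$dkappaG(s); kGpp <- fn$d2kappaG(s)
  C <- mp * sg; Cp <- mp * dsg
  sp <- sin(psi); cp <- cos(psi)
  spr <- sp / r
  psip <- 2 * H - spr
  K <- psip * spr
  HmC <- H - C
  Hp <- (f / r - kapp * HmC) / kap + Cp
  G <- (kGpp * sp + kGp * cp * psip) / r
  fp <- r * (params$p + 2 * lam * H + 2 * kap * H * HmC^2 -
               2 * kap * HmC * (2 * H^2 - K) -
               2 * H * params$alpha * sg^2 +
               2 * H * params$beta * dsg^2 + G)
  lamp <- 2 * (kap * mp * HmC + params$alpha * sg) * dsg -
    params$beta * dsg * d2sg - kapp * HmC^2 - kGp * K
  out <- rbind(cp, sp, psip, Hp, fp, lamp, deparse.level = 0)
  if (vec_in) {
    out <- drop(out)
    names(out) <- STATE_VARS
  } else rownames(out) <- STATE_VARS
  out
}

# Boundary-condition table: list of (node = "left"/"right", var index,
# target). Units follow the caller (scaled in the solver, physical in
# boundary_residuals).
bc_table <- function(mode, edge_r, lam0) {
  if (mode == "full") {
    list(list("left", 1L, edge_r),    # r(0) = R_edge
         list("left", 3L, pi / 2),    # psi(0) = pi/2
         list("left", 2L, 0),         # z(0) = 0
         list("right", 1L, edge_r),   # r(S) = R_edge
         list("right", 3L, pi / 2),   # psi(S) = pi/2
         list("right", 6L, lam0))     # lam(S) = lambda0
  } else {
    list(list("left", 2L, 0),         # z = 0 at the midpoint
         list("left", 3L, pi / 2),    # mirror symmetry: psi = pi/2
         list("left", 5L, 0),         # mirror symmetry: flux = 0
         list("right", 1L, edge_r),
         list("right", 3L, pi / 2),
         list("right", 6L, lam0))
  }
}

#' Boundary residuals of the six-point boundary-value problem
#'
#' Full-domain mode clamps radius and tangent angle at both ends
#' (r = edge radius, psi = pi/2), anchors z on the left and applies the
#' edge tension on the right. Half-domain mode (centred symmetric profiles
#' only) replaces the left clamp by mirror-symmetry conditions at the tube
#' midpoint: z = 0, psi = pi/2 and zero moment flux.
#'
#' @param left_state,right_state Named state vectors (r, z, psi, H, flux,
#'   lam) in physical units at the two ends of the solved domain.
#' @param params A [model_parameters()] object.
#' @param mode \code{"full"} or \code{"half"}.
#' @param edge_radius Clamped edge radius \[nm\]; default \code{params$Rc}.
#' @return Numeric vector of six residuals (physical units).
#' @export
boundary_residuals <- function(left_state, right_state, params,
                               mode = c("full", "half"),
                               edge_radius = NULL) {
  mode <- match.arg(mode)
  if (is.null(edge_radius)) edge_radius <- params$Rc
  pick <- function(st, i) unname(st[STATE_VARS[i]])
  bcs <- bc_table(mode, edge_radius, params$lambda0)
  vapply(bcs, function(b) {
    st <- if (b[[1]] == "left") left_state else right_state
    pick(st, b[[2]]) - b[[3]]
  }, numeric(1))
}

# --- Newton collocation core (dimensionless) -------------------------------

# Residual of the midpoint (box) scheme plus boundary rows, scaled by 1/h.
collocation_residual <- function(Y, h, fvmid, ptil, bcs, N) {
  Ymid <- (Y[, -N, drop = FALSE] + Y[, -1L, drop = FALSE]) / 2
  Fm <- rhs_material(Ymid, fvmid, ptil)
  Rint <- (Y[, -1L, drop = FALSE] - Y[, -N, drop = FALSE]) / h - Fm
  Rbc <- vapply(bcs, function(b) {
    j <- if (b[[1]] == "left") 1L else N
    Y[b[[2]], j] - b[[3]]
  }, numeric(1))
  c(as.vector(Rint), Rbc)
}

# Sparse Jacobian of collocation_residual by forward differences of the
# vectorized RHS at the interval midpoints (exact block structure).
collocation_jacobian <- function(Y, h, fvmid, ptil, bcs, N) {
  m <- N - 1L
  Ymid <- (Y[, -N, drop = FALSE] + Y[, -1L, drop = FALSE]) / 2
  F0 <- rhs_material(Ymid, fvmid, ptil)
  J <- array(0, dim = c(6L, 6L, m))
  for (j in 1:6) {
    dj <- 1e-7 * (1 + abs(Ymid[j, ]))
    Yp <- Ymid
    Yp[j, ] <- Yp[j, ] + dj
    Fp <- rhs_material(Yp, fvmid, ptil)
    J[, j, ] <- (Fp - F0) / rep(dj, each = 6L)
  }
  nint <- 72L * m
  ii <- integer(nint + 6L); jj <- integer(nint + 6L); xx <- numeric(nint + 6L)
  pos <- 0L
  base <- 6L * (0:(m - 1L))
  for (a in 1:6) {
    for (b in 1:6) {
      idx <- pos + seq_len(m)
      ii[idx] <- base + a
      jj[idx] <- base + b
      xx[idx] <- -0.5 * J[a, b, ] - (a == b) / h
      pos <- pos + m
      idx <- pos + seq_len(m)
      ii[idx] <- base + a
      jj[idx] <- base + b + 6L
      xx[idx] <- -0.5 * J[a, b, ] + (a == b) / h
      pos <- pos + m
    }
  }
  for (k in seq_along(bcs)) {
    b <- bcs[[k]]
    ii[pos + k] <- 6L * m + k
    jj[pos + k] <- if (b[[1]] == "left") b[[2]] else 6L * (N - 1L) + b[[2]]
    xx[pos + k] <- 1
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(6L * N, 6L * N))
}

newton_collocation <- function(Y, h, fvmid, ptil, bcs, tol, max_iter) {
  N <- ncol(Y)
  res <- collocation_residual(Y, h, fvmid, ptil, bcs, N)
  normF <- max(abs(res))
  iter <- 0L
  while (normF > tol && iter < max_iter) {
    iter <- iter + 1L
    A <- collocation_jacobian(Y, h, fvmid, ptil, bcs, N)
    dY <- tryCatch(as.numeric(Matrix::solve(A, -res)),
                   error = function(e) NULL)
    if (is.null(dY) || !all(is.finite(dY)))
      return(list(Y = Y, residual = normF, converged = FALSE, iter = iter))
    dY <- matrix(dY, nrow = 6L)
    accepted <- FALSE
    fac <- 1
    for (ls in 1:10) {
      Yt <- Y + fac * dY
      if (min(Yt[1L, ]) > 0.02) {
        rt <- collocation_residual(Yt, h, fvmid, ptil, bcs, N)
        nt <- max(abs(rt))
        if (is.finite(nt) && (nt < normF * (1 - 0.2 * fac) || nt < tol)) {
          Y <- Yt; res <- rt; normF <- nt; accepted <- TRUE
          break
        }
      }
      fac <- fac / 2
    }
    if (!accepted)
      return(list(Y = Y, residual = normF, converged = FALSE, iter = iter))
  }
  list(Y = Y, residual = normF, converged = normF <= tol, iter = iter)
}

# --- user-facing solve ------------------------------------------------------

profile_is_symmetric <- function(fields) {
  L <- fields$L_total
  sprobe <- seq(0, L / 2, length.out = 61)
  for (f in c("sigma", "kappa", "kappaG")) {
    a <- fields$funs[[f]](sprobe)
    b <- fields$funs[[f]](L - sprobe)
    scale <- max(abs(a), abs(b), 1e-300)
    if (max(abs(a - b)) > 1e-9 * scale) return(FALSE)
  }
  TRUE
}

default_guess <- function(N, tgrid, edge_r_scaled, lam0til) {
  Y <- matrix(0, nrow = 6L, ncol = N)
  Y[1L, ] <- edge_r_scaled
  Y[2L, ] <- tgrid / edge_r_scaled
  Y[3L, ] <- pi / 2
  Y[4L, ] <- 1 / (2 * edge_r_scaled)
  Y[5L, ] <- 0
  Y[6L, ] <- lam0til
  Y
}

# Interpolate a previous solution (full physical membrane_shape) onto the
# scaled solver grid (material coordinate).
guess_from_shape <- function(shape, tgrid, params, half) {
  sc <- state_scale(params)
  off <- if (half) params$Lc / 2 else 0
  u_new <- off + tgrid * params$Rc
  Y <- matrix(0, nrow = 6L, ncol = length(tgrid))
  src <- rbind(shape$r, shape$z, shape$psi, shape$H, shape$flux, shape$lam)
  for (i in 1:6) {
    Y[i, ] <- stats::approx(shape$u, src[i, ], xout = u_new, rule = 2)$y * sc[i]
  }
  if (half) Y[2L, ] <- Y[2L, ] - Y[2L, 1L]  # re-anchor z at the midpoint
  Y
}

#' Solve the equilibrium shape of a heterogeneous nanotube
#'
#' Solves the six-field axisymmetric boundary-value problem (shape equation
#' plus tension equation) by Newton iteration on a midpoint collocation
#' scheme. The independent variable is the material (area) coordinate u of
#' the locally incompressible membrane: the tube carries a fixed membrane
#' area 2 pi Rc Lc, the heterogeneity fields are material fields sigma(u),
#' kappa(u), kappa_G(u), and the deformed arclength follows from
#' ds = (Rc/r) du. The transmembrane pressure is taken from \code{params}
#' (default 0). For strongly heterogeneous inputs seed the solve from a
#' neighbouring solution via \code{guess} or use [continuation()].
#'
#' @param fields A \code{profile_set} defined on \[0, Lc\] (material
#'   coordinate).
#' @param params A [model_parameters()] object.
#' @param guess Optional \code{membrane_shape} used as the initial iterate;
#'   default is the uniform cylinder at the edge radius.
#' @param config A [solver_config()].
#' @return A \code{membrane_shape}: samples (indexed by the material
#'   coordinate \code{u}) of the deformed arclength \code{s}, r, z, psi, H,
#'   flux, tension lam, Gaussian curvature K and the local fields, plus
#'   convergence metadata. Always covers the full tube, also in
#'   half-domain mode.
#' @export
#' @examples
#' pars <- model_parameters()
#' tube <- solve_shape(homogeneous_profiles(pars), pars,
#'                     config = solver_config(mesh_size = 401))
#' max(tube$r)  # ~35.4 nm: the equilibrium tether radius at 0.064 pN/nm
solve_shape <- function(fields, params, guess = NULL,
                        config = solver_config()) {
  stopifnot(inherits(fields, "profile_set"),
            inherits(params, "model_parameters"))
  if (abs(fields$L_total - params$Lc) > 1e-6 * params$Lc)
    stop("fields are defined on [0, ", fields$L_total,
         "] but params$Lc = ", params$Lc)
  mode <- config$symmetry_mode
  if (mode == "auto")
    mode <- if (profile_is_symmetric(fields)) "half" else "full"
  if (mode == "half" && !profile_is_symmetric(fields))
    stop("half-domain mode requires profiles symmetric about the tube midpoint")
  half <- mode == "half"

  Rc <- params$Rc
  S <- if (half) params$Lc / 2 else params$Lc
  N <- config$mesh_size
  tgrid <- seq(0, S / Rc, length.out = N)
  h <- tgrid[2L] - tgrid[1L]
  edge_r <- if (is.null(config$edge_radius)) Rc else config$edge_radius
  sf <- scaled_fields(fields, params, offset = if (half) params$Lc / 2 else 0)
  fvmid <- sf$eval((tgrid[-N] + tgrid[-1L]) / 2)
  bcs <- bc_table(mode, edge_r / Rc, sf$lam0til)

  Y0 <- if (is.null(guess)) {
    default_guess(N, tgrid, edge_r / Rc, sf$lam0til)
  } else {
    stopifnot(inherits(guess, "membrane_shape"))
    guess_from_shape(guess, tgrid, params, half)
  }

  fit <- newton_collocation(Y0, h, fvmid, sf$ptil, bcs,
                            config$tolerance, config$max_iter)
  if (!fit$converged)
    stop("collocation solve did not converge (residual ",
         format(fit$residual, digits = 3),
         "); seed from a closer solution or use continuation()",
         call. = FALSE)
  assemble_shape(fit, tgrid, fields, params, config, mode, edge_r)
}

assemble_shape <- function(fit, tgrid, fields, params, config, mode, edge_r) {
  Rc <- params$Rc; k0 <- params$kappa
  Y <- fit$Y
  if (mode == "half") {
    n <- ncol(Y)
    zh <- Y[2L, ]
    u <- c(params$Lc / 2 - rev(tgrid) * Rc,
           (params$Lc / 2 + tgrid * Rc)[-1L])
    r <- c(rev(Y[1L, ]), Y[1L, -1L]) * Rc
    z <- c(rev(zh[n] - zh), (zh[n] + zh)[-1L]) * Rc
    psi <- c(rev(pi - Y[3L, ]), Y[3L, -1L])
    H <- c(rev(Y[4L, ]), Y[4L, -1L]) / Rc
    flux <- c(rev(-Y[5L, ]), Y[5L, -1L]) * k0 / Rc
    lam <- c(rev(Y[6L, ]), Y[6L, -1L]) * k0 / Rc^2
  } else {
    u <- tgrid * Rc
    r <- Y[1L, ] * Rc
    z <- Y[2L, ] * Rc
    psi <- Y[3L, ]
    H <- Y[4L, ] / Rc
    flux <- Y[5L, ] * k0 / Rc
    lam <- Y[6L, ] * k0 / Rc^2
  }
  # deformed arclength from the area map ds = (Rc/r) du
  du <- diff(u)
  stretch <- Rc / r
  s <- c(0, cumsum(du * (stretch[-1L] + stretch[-length(stretch)]) / 2))
  psip <- 2 * H - sin(psi) / r
  K <- psip * sin(psi) / r
  structure(list(
    u = u, s = s, r = r, z = z, psi = psi, H = H, flux = flux, lam = lam,
    K = K,
    sigma = fields$funs$sigma(u), dsigma_du = fields$funs$dsigma(u),
    kappa = fields$funs$kappa(u), kappaG = fields$funs$kappaG(u),
    params = params, config = config, mode = mode, edge_radius = edge_r,
    converged = TRUE, residual = fit$residual, iterations = fit$iter
  ), class = "membrane_shape")
}

#' @export
print.membrane_shape <- function(x, ...) {
  cat("Axisymmetric membrane shape (", x$mode, "-domain solve, ",
      length(x$u), " samples)\n", sep = "")
  cat(sprintf("  membrane area %.4g nm^2, axial extent %.4g nm\n",
              2 * pi * x$params$Rc * max(x$u), max(x$z) - min(x$z)))
  cat(sprintf("  r: %.4g - %.4g nm; max |H| %.4g nm^-1\n",
              min(x$r), max(x$r), max(abs(x$H))))
  cat(sprintf("  tension: %.4g - %.4g pN/nm\n", min(x$lam), max(x$lam)))
  cat(sprintf("  converged (residual %.3g, %d Newton iterations)\n",
              x$residual, x$iterations))
  invisible(x)
}

#' @export
as.data.frame.membrane_shape <- function(x, ...) {
  data.frame(u_nm = x$u, s_nm = x$s, r_nm = x$r, z_nm = x$z,
             psi_rad = x$psi, H_per_nm = x$H, K_per_nm2 = x$K,
             lambda_pN_per_nm = x$lam, sigma_nm2 = x$sigma)
}

#' Export a solved shape as CSV
#'
#' Columns: \code{u_nm, s_nm, r_nm, z_nm, psi_rad, H_per_nm, K_per_nm2,
#' lambda_pN_per_nm, sigma_nm2} (material coordinate, deformed arclength,
#' then the state).
#'
#' @param shape A \code{membrane_shape}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_shape_csv <- function(shape, path) {
  utils::write.csv(as.data.frame(shape), path, row.names = FALSE)
  invisible(path)
}

#' Discrete-scheme consistency of a solved shape
#'
#' Recomputes the midpoint-scheme defects of the geometric relations
#' (dr/ds = cos psi, dz/ds = sin psi, 2H = dpsi/ds + sin(psi)/r, with
#' d/ds = (r/Rc) d/du on the material mesh) in dimensionless form. All
#' three are bounded by the collocation tolerance for a converged shape.
#'
#' @param shape A \code{membrane_shape}.
#' @return Named numeric vector of max-norm defects
#'   (\code{dr}, \code{dz}, \code{curv}).
#' @export
shape_consistency <- function(shape) {
  Rc <- shape$params$Rc
  t <- shape$u / Rc; r <- shape$r / Rc; z <- shape$z / Rc
  psi <- shape$psi; H <- shape$H * Rc
  h <- diff(t)
  mid <- function(v) (v[-1L] + v[-length(v)]) / 2
  rm <- mid(r)
  dr <- diff(r) / h - cos(mid(psi)) / rm
  dz <- diff(z) / h - sin(mid(psi)) / rm
  curv <- diff(psi) / h - (2 * mid(H) - sin(mid(psi)) / rm) / rm
  c(dr = max(abs(dr)), dz = max(abs(dz)), curv = max(abs(curv)))
}

# --- continuation -----------------------------------------------------------

#' Parameter continuation of equilibrium shapes
#'
#' Solves a family of boundary-value problems along a parameter path,
#' seeding each solve with the previous solution. Failed steps are
#' recursively bisected up to \code{config$step_halving_limit} times; if a
#' step still fails the branch is truncated (with a diagnostic attribute),
#' not an error. Consecutive converged shapes whose radial profiles jump by
#' more than ten times the median step change are flagged as
#' discontinuities.
#'
#' @param values Ordered numeric parameter values to visit.
#' @param setup Function of one parameter value returning
#'   \code{list(fields = <profile_set>, params = <model_parameters>)}.
#' @param config A [solver_config()].
#' @param guess Optional \code{membrane_shape} seeding the first value.
#' @param param_name Label stored in the branch.
#' @return A \code{continuation_branch}: the values, one shape per
#'   converged value, an energy/measurement table, convergence flags and
#'   discontinuity flags.
#' @export
continuation <- function(values, setup, config = solver_config(),
                         guess = NULL, param_name = "parameter") {
  nv <- length(values)
  shapes <- vector("list", nv)
  converged <- logical(nv)
  truncated_at <- NA_integer_

  advance <- function(prev, v_from, v_to, depth) {
    st <- setup(v_to)
    sol <- tryCatch(solve_shape(st$fields, st$params, guess = prev, config),
                    error = function(e) NULL)
    if (!is.null(sol)) return(sol)
    if (depth <= 0L) return(NULL)
    v_mid <- (v_from + v_to) / 2
    smid <- advance(prev, v_from, v_mid, depth - 1L)
    if (is.null(smid)) return(NULL)
    advance(smid, v_mid, v_to, depth - 1L)
  }

  prev <- guess
  v_prev <- NULL
  for (i in seq_len(nv)) {
    sol <- if (is.null(v_prev)) {
      st <- setup(values[i])
      tryCatch(solve_shape(st$fields, st$params, guess = prev, config),
               error = function(e) NULL)
    } else {
      advance(prev, v_prev, values[i], config$step_halving_limit)
    }
    if (is.null(sol)) {
      truncated_at <- i
      break
    }
    shapes[[i]] <- sol
    converged[i] <- TRUE
    prev <- sol
    v_prev <- values[i]
  }

  ok <- which(converged)
  r_b <- rep(NA_real_, nv); min_lam <- rep(NA_real_, nv)
  energy <- rep(NA_real_, nv)
  for (i in ok) {
    r_b[i] <- max(shapes[[i]]$r)
    min_lam[i] <- min(shapes[[i]]$lam)
    st <- setup(values[i])
    energy[i] <- total_energy(shapes[[i]], st$fields, st$params)$total
  }
  jumps <- rep(FALSE, nv)
  if (length(ok) > 2L) {
    steps <- numeric(0)
    for (k in seq_along(ok)[-1L]) {
      i0 <- ok[k - 1L]; i1 <- ok[k]
      d <- sqrt(mean((shapes[[i1]]$r - shapes[[i0]]$r)^2))
      steps <- c(steps, d)
    }
    med <- stats::median(steps)
    if (med > 0)
      for (k in seq_along(steps))
        if (steps[k] > 10 * med) jumps[ok[k + 1L]] <- TRUE
  }
  structure(list(parameter = param_name, values = values, shapes = shapes,
                 converged = converged,
                 table = data.frame(value = values, converged = converged,
                                    r_b_nm = r_b, min_lambda_pN_per_nm = min_lam,
                                    energy_pNnm = energy, jump = jumps),
                 truncated_at = truncated_at),
            class = "continuation_branch")
}

#' @export
print.continuation_branch <- function(x, ...) {
  cat("Continuation branch in '", x$parameter, "' (",
      sum(x$converged), "/", length(x$values), " converged)\n", sep = "")
  if (!is.na(x$truncated_at))
    cat("  truncated at value index", x$truncated_at, "\n")
  print(utils::head(x$table, 12))
  if (nrow(x$table) > 12) cat("  ...\n")
  invisible(x)
}
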