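trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Total membrane energy of a solved shape, by component
#'
#' Integrates each energy density over the membrane surface: curvature-
#' elastic (bending) energy, Gaussian term, protein aggregation, density-
#' gradient penalty and, when enabled, the entropic mixing term. Because
#' the membrane is locally area-incompressible, the area element is uniform
#' in the material coordinate (dA = 2 pi Rc du) and the quadrature is
#' trapezoidal on the material mesh; the density gradient is the surface
#' gradient, d sigma/ds = (r/Rc) d sigma/du.
#'
#' @param shape A \code{membrane_shape}.
#' @param fields A \code{profile_set}; must cover the material range of
#'   the shape. Defaults to the fields sampled into the shape at solve
#'   time.
#' @param params A [model_parameters()] object; defaults to the shape's.
#' @return An object of class \code{"energy_breakdown"}: named list with
#'   \code{bending}, \code{gaussian}, \code{aggregation}, \code{gradient},
#'   \code{entropic} and \code{total} \[pN nm\].
#' @export
#' @examples
#' pars <- model_parameters()
#' tube <- solve_shape(homogeneous_profiles(pars), pars,
#'                     config = solver_config(mesh_size = 401))
#' total_energy(tube)  # ~ kappa/(4 Rc^2) * 2 pi Rc Lc for the bare tube
total_energy <- function(shape, fields = NULL, params = NULL) {
  stopifnot(inherits(shape, "membrane_shape"))
  if (is.null(params)) params <- shape$params
  if (is.null(fields)) {
    sg <- shape$sigma; dsg_du <- shape$dsigma_du
    kap <- shape$kappa; kG <- shape$kappaG
  } else {
    if (min(shape$u) < -1e-9 || max(shape$u) > fields$L_total * (1 + 1e-9))
      stop("shape material range is not covered by the fields grid")
    sg <- fields$funs$sigma(shape$u)
    dsg_du <- fields$funs$dsigma(shape$u)
    kap <- fields$funs$kappa(shape$u)
    kG <- fields$funs$kappaG(shape$u)
  }
  dA <- 2 * pi * params$Rc          # area element per unit material length
  dsg_ds <- (shape$r / params$Rc) * dsg_du
  C <- params$mu * params$phi * sg
  u <- shape$u
  comp <- list(
    bending = trapz(u, kap * (shape$H - C)^2) * dA,
    gaussian = trapz(u, kG * shape$K) * dA,
    aggregation = trapz(u, -params$alpha * sg^2) * dA,
    gradient = trapz(u, params$beta * dsg_ds^2) * dA
  )
  comp$entropic <- if (params$include_entropy) {
    went <- ifelse(sg > 0,
                   params$kBT * sg * (log(sg / params$sigma_s) - 1), 0)
    trapz(u, went) * dA
  } else 0
  comp$total <- comp$bending + comp$gaussian + comp$aggregation +
    comp$gradient + comp$entropic
  structure(comp, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Membrane energy breakdown [pN nm]\n")
  for (f in c("bending", "gaussian", "aggregation", "gradient", "entropic"))
    cat(sprintf("  %-12s %14.6g\n", f, x[[f]]))
  cat(sprintf("  %-12s %14.6g\n", "total", x$total))
  invisible(x)
}
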