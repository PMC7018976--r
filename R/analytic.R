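#' Protein-induced spontaneous curvature
#'
#' In the dilute regime the spontaneous curvature induced by cone-shaped
#' membrane inclusions is linear in the surface protein density:
#' C(sigma) = mu * phi * sigma. With phi < 0 the induced curvature is
#' negative wherever proteins are present.
#'
#' @param sigma Protein density \[nm^-2\], >= 0. Vectorized.
#' @param params A [model_parameters()] object.
#' @return Spontaneous curvature \[nm^-1\].
#' @export
#' @examples
#' spontaneous_curvature(1.25e-4, model_parameters())  # -0.025 nm^-1
spontaneous_curvature <- function(sigma, params) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  params$mu * params$phi * sigma
}

#' Protein contribution to the energy density
#'
#' Energy per unit area from protein-protein interactions:
#' \deqn{W_p = -\alpha \sigma^2 + \beta (\sigma')^2
#'       [+ k_BT \sigma (\log(\sigma/\sigma_s) - 1)]}
#' The entropic bracket is included only when
#' \code{params$include_entropy} is TRUE; its sigma -> 0 limit is 0.
#'
#' @param sigma Protein density \[nm^-2\]. Vectorized.
#' @param dsigma_ds Arclength derivative of the density \[nm^-3\].
#' @param params A [model_parameters()] object.
#' @return Energy per unit area \[pN/nm\].
#' @export
protein_energy_density <- function(sigma, dsigma_ds, params) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  w <- -params$alpha * sigma^2 + params$beta * dsigma_ds^2
  if (params$include_entropy) {
    ent <- ifelse(sigma > 0,
                  params$kBT * sigma * (log(sigma / params$sigma_s) - 1),
                  0)
    w <- w + ent
  }
  w
}

#' Curvature-elastic energy density of the heterogeneous membrane
#'
#' Helfrich bending energy per unit area with position-dependent moduli and
#' protein-induced spontaneous curvature:
#' \deqn{W_b = \kappa(s) [H - C(\sigma)]^2 + \kappa_G(s) K.}
#'
#' @param H Mean curvature \[nm^-1\]. Vectorized.
#' @param K Gaussian curvature \[nm^-2\].
#' @param sigma Protein density \[nm^-2\].
#' @param kappa_local Local bending rigidity \[pN nm\], > 0.
#' @param kappaG_local Local Gaussian modulus \[pN nm\].
#' @param params A [model_parameters()] object.
#' @return Energy per unit area \[pN/nm\].
#' @export
bending_energy_density <- function(H, K, sigma, kappa_local, kappaG_local,
                                   params) {
  if (any(kappa_local <= 0)) stop("kappa_local must be positive")
  C <- spontaneous_curvature(sigma, params)
  kappa_local * (H - C)^2 + kappaG_local * K
}

#' Induced length scales of the two heterogeneity mechanisms
#'
#' The rigid domain sets a tether-like scale
#' \eqn{l_\kappa = \frac{1}{2}\sqrt{\kappa_{protein}/\lambda}}, the protein
#' aggregation a curvature scale \eqn{l_\sigma = 1/|\mu\varphi\sigma_0|}
#' (the magnitude is taken so the length is positive for cone-shaped
#' proteins with phi < 0). Their log-ratio organizes the bead-shape phase
#' diagram: ellipsoidal beads for log10 > 0, cylindrical near 0, unduloid
#' for log10 < 0.
#'
#' @param sigma0 Plateau protein density \[nm^-2\].
#' @param lambda_val Membrane tension \[pN/nm\], > 0.
#' @param kappa_protein Bending rigidity of the domain \[pN nm\], > 0.
#' @param params A [model_parameters()] object.
#' @return List with \code{l_sigma}, \code{l_kappa} \[nm\] and
#'   \code{log_ratio} = log10(l_sigma / l_kappa). \code{sigma0 = 0} gives
#'   \code{l_sigma = Inf} and \code{log_ratio = Inf} (flagged, not an error).
#' @export
#' @examples
#' induced_length_scales(1.25e-4, 0.064, 320, model_parameters())
induced_length_scales <- function(sigma0, lambda_val, kappa_protein, params) {
  if (lambda_val <= 0) stop("lambda_val must be positive")
  if (kappa_protein <= 0) stop("kappa_protein must be positive")
  if (sigma0 < 0) stop("sigma0 must be non-negative")
  l_kappa <- 0.5 * sqrt(kappa_protein / lambda_val)
  l_sigma <- if (sigma0 > 0) 1 / abs(params$mu * params$phi * sigma0) else Inf
  list(l_sigma = l_sigma, l_kappa = l_kappa,
       log_ratio = log10(l_sigma / l_kappa))
}

#' Mean curvature at the centre of the protein-enriched domain (limit case)
#'
#' Closed-form limit obtained by equating the local energy density in the
#' domain to the bare-tube density \eqn{W_0 = \kappa H_0^2}:
#' \deqn{H = \mu\varphi\sigma + \sqrt{\frac{1/(2R_c)^2 + \alpha\sigma^2/\kappa
#'        - \beta(\nabla\sigma)^2/\kappa}{\kappa_{ratio}}}.}
#' Evaluated at the domain centre, where the density gradient vanishes by
#' symmetry, so \code{grad_sigma} defaults to 0.
#'
#' @param sigma Plateau protein density \[nm^-2\].
#' @param kappa_ratio Rigidity ratio of the domain to the bare membrane, > 0.
#' @param params A [model_parameters()] object.
#' @param grad_sigma Representative density gradient \[nm^-3\], default 0.
#' @return Mean curvature \[nm^-1\].
#' @export
#' @examples
#' mean_curvature_center(2.5e-5, 1, model_parameters())  # ~0.010135 nm^-1
mean_curvature_center <- function(sigma, kappa_ratio, params,
                                  grad_sigma = 0) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (kappa_ratio <= 0) stop("kappa_ratio must be positive")
  rad <- (1 / (2 * params$Rc)^2 + params$alpha * sigma^2 / params$kappa -
            params$beta * grad_sigma^2 / params$kappa) / kappa_ratio
  if (any(rad < 0))
    stop("negative radicand: the gradient-penalty term beta*(grad sigma)^2 ",
         "exceeds the curvature and aggregation terms")
  params$mu * params$phi * sigma + sqrt(rad)
}

#' Linearized mean curvature at the domain centre
#'
#' First-order Taylor expansion of [mean_curvature_center()] for low protein
#' density:
#' \deqn{H = \mu\varphi\sigma + \frac{1}{\sqrt{\kappa_{ratio}}}
#'       \left[\frac{1}{2R_c} + \frac{R_c}{\kappa}(\alpha\sigma^2 -
#'       \beta(\nabla\sigma)^2)\right].}
#'
#' @inheritParams mean_curvature_center
#' @return Mean curvature \[nm^-1\].
#' @export
mean_curvature_center_linearized <- function(sigma, kappa_ratio, params,
                                             grad_sigma = 0) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (kappa_ratio <= 0) stop("kappa_ratio must be positive")
  params$mu * params$phi * sigma +
    (1 / sqrt(kappa_ratio)) *
    (1 / (2 * params$Rc) +
       (params$Rc / params$kappa) *
       (params$alpha * sigma^2 - params$beta * grad_sigma^2))
}

#' Bead radius in the cylindrical-bead approximation
#'
#' Approximates the bead as a cylinder, so its radius is
#' \eqn{r_b = 1/(2 H)} with H from [mean_curvature_center()]. Valid only
#' while that curvature is positive; at high protein density and rigidity
#' ratio the limit curvature changes sign and no rotationally symmetric
#' cylinder matches it, so an error is raised.
#'
#' @inheritParams mean_curvature_center
#' @return Bead radius \[nm\].
#' @export
#' @examples
#' bead_radius_analytic(2.5e-5, 1, model_parameters())  # ~49.3 nm
bead_radius_analytic <- function(sigma, kappa_ratio, params,
                                 grad_sigma = 0) {
  H <- mean_curvature_center(sigma, kappa_ratio, params, grad_sigma)
  if (any(H <= 0))
    stop("limit mean curvature is non-positive (the regime where its sign ",
         "changes from positive to negative); the cylindrical-bead ",
         "approximation does not apply")
  1 / (2 * H)
}

#' Linearized bead radius for low protein density
#'
#' \deqn{r_b = \sqrt{\kappa_{ratio}} R_c [1 - 2 R_c \sqrt{\kappa_{ratio}}
#'       \mu\varphi\sigma - \frac{2R_c^2}{\kappa}(\alpha\sigma^2 -
#'       \beta(\nabla\sigma)^2)].}
#'
#' @inheritParams mean_curvature_center
#' @return Bead radius \[nm\].
#' @export
bead_radius_linearized <- function(sigma, kappa_ratio, params,
                                   grad_sigma = 0) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (any(kappa_ratio <= 0)) stop("kappa_ratio must be positive")
  sqrt(kappa_ratio) * params$Rc *
    (1 - 2 * params$Rc * sqrt(kappa_ratio) *
       (params$mu * params$phi * sigma) -
       (2 * params$Rc^2 / params$kappa) *
       (params$alpha * sigma^2 - params$beta * grad_sigma^2))
}

#' Equilibrium radius of a uniform membrane cylinder
#'
#' The homogeneous shape equation with zero pressure and no protein is
#' satisfied by a cylinder of radius \eqn{R = \frac{1}{2}\sqrt{\kappa/\lambda}}
#' (tension balances bending). This is the tether radius and the primary
#' closed-form oracle for the collocation solver.
#'
#' @param kappa_val Bending rigidity \[pN nm\].
#' @param lambda_val Membrane tension \[pN/nm\], > 0.
#' @return Radius \[nm\].
#' @export
#' @examples
#' equilibrium_tube_radius(320, 0.064)  # ~35.36 nm
equilibrium_tube_radius <- function(kappa_val, lambda_val) {
  if (any(lambda_val <= 0))
    stop("lambda_val must be positive (zero tension gives an unbounded radius)")
  if (any(kappa_val <= 0)) stop("kappa_val must be positive")
  0.5 * sqrt(kappa_val / lambda_val)
}
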