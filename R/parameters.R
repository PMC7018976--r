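#' Physical parameters of the heterogeneous-nanotube model
#'
#' Container for all physical constants of the model. Defaults are the
#' parameter set used throughout the bead-formation studies: a bare-membrane
#' bending rigidity of 320 pN nm, a protein aggregation strength of
#' 1.28e7 pN nm^3, a lipid--protein length scale of 200 nm, a cone angle of
#' -1 (cone-shaped proteins inducing negative spontaneous curvature), zero
#' transmembrane pressure, and a 35 nm x 20 um nanotube held at an edge
#' tension of 0.064 pN/nm.
#'
#' @param kappa Bending rigidity of the bare lipid membrane \[pN nm\].
#' @param alpha Strength of attractive protein-protein interactions
#'   \[pN nm^3\].
#' @param beta Penalty on protein-density gradients \[pN nm^4\]. Not part of
#'   the tabulated parameter set; defaults to 0 (gradient term off). See
#'   Details for a documented nonzero example value.
#' @param mu Lipid-protein length scale entering the spontaneous curvature
#'   \[nm\].
#' @param phi Cone angle of the protein inclusions \[dimensionless\].
#'   Negative for cone-shaped proteins; set \code{phi = 0} to model
#'   cylindrical inclusions that change composition without inducing
#'   curvature (the "C = 0" studies).
#' @param lambda0 Membrane tension applied at the tube edge \[pN/nm\].
#' @param p Transmembrane pressure \[pN/nm^2\], default 0.
#' @param Rc Nanotube radius \[nm\].
#' @param Lc Nanotube length \[nm\].
#' @param kBT Thermal energy \[pN nm\].
#' @param sigma_s Saturation protein density \[nm^-2\]; used only by the
#'   entropic term.
#' @param include_entropy Logical; include the entropic mixing term in the
#'   protein energy density. Off by default: for bending rigidities of
#'   20-40 kBT and dilute densities (kBT * sigma << 1) the term is
#'   negligible against the bending energy.
#'
#' @details
#' \code{beta} multiplies the squared protein-density gradient. A documented
#' nonzero example is \code{beta = 3.2e11} pN nm^4: for the default
#' single-domain profile (amplitude 1.25e-4 nm^-2, transition width 350 nm)
#' the peak gradient is about sigma0/(2 w), so
#' beta * (sigma')^2 is under 10 percent of alpha * sigma^2 at the
#' transition and zero at the plateau. All headline results use
#' \code{beta = 0}.
#'
#' @return An object of class \code{"model_parameters"} (a named list).
#' @seealso [read_parameters()] to load from a YAML file.
#' @export
#' @examples
#' pars <- model_parameters()
#' pars$kappa
#' # cylindrical inclusions: rigidity heterogeneity without curvature
#' model_parameters(phi = 0)
model_parameters <- function(kappa = 320,
                             alpha = 1.28e7,
                             beta = 0,
                             mu = 200,
                             phi = -1,
                             lambda0 = 0.064,
                             p = 0,
                             Rc = 35,
                             Lc = 2e4,
                             kBT = 4.114,
                             sigma_s = 3.75e-4,
                             include_entropy = FALSE) {
  pars <- list(kappa = kappa, alpha = alpha, beta = beta, mu = mu,
               phi = phi, lambda0 = lambda0, p = p, Rc = Rc, Lc = Lc,
               kBT = kBT, sigma_s = sigma_s,
               include_entropy = isTRUE(include_entropy))
  validate_parameters(pars)
  class(pars) <- "model_parameters"
  pars
}

validate_parameters <- function(pars) {
  num_fields <- c("kappa", "alpha", "beta", "mu", "phi", "lambda0", "p",
                  "Rc", "Lc", "kBT", "sigma_s")
  for (f in num_fields) {
    v <- pars[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (pars$kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (pars$Rc <= 0) stop("Rc must be positive", call. = FALSE)
  if (pars$Lc <= 0) stop("Lc must be positive", call. = FALSE)
  if (pars$lambda0 < 0) stop("lambda0 must be non-negative", call. = FALSE)
  if (pars$phi > 0)
    stop("phi must be <= 0: inclusions are cone-shaped (phi < 0) or ",
         "cylindrical (phi = 0)", call. = FALSE)
  if (pars$include_entropy && pars$sigma_s <= 0)
    stop("sigma_s must be positive when the entropic term is enabled",
         call. = FALSE)
  invisible(pars)
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a flat YAML mapping whose keys are the argument names of
#' [model_parameters()] (units as documented there). Keys that are not
#' recognized parameters are rejected, so typos fail loudly rather than
#' silently falling back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A \code{model_parameters} object.
#' @export
read_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("parameter file must contain a YAML mapping")
  known <- names(formals(model_parameters))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(model_parameters, cfg)
}

#' Write model parameters to a YAML configuration file
#'
#' @param pars A \code{model_parameters} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(pars, path) {
  stopifnot(inherits(pars, "model_parameters"))
  yaml::write_yaml(unclass(pars), path)
  invisible(path)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Membrane nanotube model parameters\n")
  cat(sprintf("  kappa   %10.4g pN nm    (bare bending rigidity)\n", x$kappa))
  cat(sprintf("  alpha   %10.4g pN nm^3  (protein aggregation strength)\n",
              x$alpha))
  cat(sprintf("  beta    %10.4g pN nm^4  (gradient penalty)\n", x$beta))
  cat(sprintf("  mu      %10.4g nm       (lipid-protein length scale)\n",
              x$mu))
  cat(sprintf("  phi     %10.4g          (protein cone angle)\n", x$phi))
  cat(sprintf("  lambda0 %10.4g pN/nm    (edge tension)\n", x$lambda0))
  cat(sprintf("  p       %10.4g pN/nm^2  (transmembrane pressure)\n", x$p))
  cat(sprintf("  Rc      %10.4g nm, Lc %.4g nm (tube radius, length)\n",
              x$Rc, x$Lc))
  cat(sprintf("  kBT     %10.4g pN nm; entropic term %s (sigma_s = %.3g)\n",
              x$kBT, if (x$include_entropy) "on" else "off", x$sigma_s))
  invisible(x)
}
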