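#' Specify one heterogeneous domain along the tube
#'
#' A domain is a plateau of a field (protein density, bending rigidity, or
#' Gaussian modulus) with smooth hyperbolic-tangent shoulders. The plateau
#' covers \code{length} of arclength centred at \code{center}; each shoulder
#' has half-width \code{transition_width}.
#'
#' @param center Arclength position of the domain centre \[nm\].
#' @param length Covered (plateau) length of the domain \[nm\].
#' @param amplitude Plateau value of the field (e.g. sigma0 in nm^-2 for a
#'   protein domain, or kappa_ratio * kappa in pN nm for a rigid domain).
#' @param transition_width tanh transition half-width w \[nm\]. Must satisfy
#'   0 < w <= length/2; the default profile builders use
#'   \code{min(10 * Rc, length/20)}.
#' @return An object of class \code{"domain_spec"}.
#' @export
domain_spec <- function(center, length, amplitude, transition_width) {
  if (!(length > 0)) stop("domain length must be positive")
  if (!(transition_width > 0)) stop("transition_width must be positive")
  if (transition_width > length / 2)
    stop("transition_width must be small compared to the domain length ",
         "(at most length/2)")
  structure(list(center = center, length = length, amplitude = amplitude,
                 transition_width = transition_width),
            class = "domain_spec")
}

# Smooth bump of unit plateau height for one domain: 0 outside, 1 on the
# plateau, tanh shoulders of half-width w. deriv = 0, 1, 2 selects the
# analytic derivative order with respect to s.
domain_bump <- function(s, dom, deriv = 0L) {
  w <- dom$transition_width
  a <- dom$center - dom$length / 2
  b <- dom$center + dom$length / 2
  ua <- (s - a) / w
  ub <- (s - b) / w
  if (deriv == 0L) {
    (tanh(ua) - tanh(ub)) / 2
  } else if (deriv == 1L) {
    (1 / cosh(ua)^2 - 1 / cosh(ub)^2) / (2 * w)
  } else {
    (-2 * tanh(ua) / cosh(ua)^2 + 2 * tanh(ub) / cosh(ub)^2) / (2 * w^2)
  }
}

domains_overlap <- function(d1, d2) {
  a1 <- d1$center - d1$length / 2; b1 <- d1$center + d1$length / 2
  a2 <- d2$center - d2$length / 2; b2 <- d2$center + d2$length / 2
  max(a1, a2) < min(b1, b2)   # strict: touching (L_separation = 0) is fine
}

check_domains <- function(domains, L_total) {
  for (d in domains) {
    stopifnot(inherits(d, "domain_spec"))
    if (d$center - d$length / 2 < 0 || d$center + d$length / 2 > L_total)
      stop("domain [", d$center - d$length / 2, ", ",
           d$center + d$length / 2, "] nm extends outside the tube [0, ",
           L_total, "] nm")
  }
  if (length(domains) > 1L) {
    for (i in seq_len(length(domains) - 1L)) {
      for (j in seq(i + 1L, length(domains))) {
        if (domains_overlap(domains[[i]], domains[[j]]) &&
            domains[[i]]$amplitude != domains[[j]]$amplitude)
          stop("overlapping domains with different amplitudes are ",
               "ambiguous; separate them or give them equal amplitudes")
      }
    }
  }
  invisible(TRUE)
}

#' Evaluate a tanh heterogeneity field
#'
#' Builds a field that equals \code{baseline} far from all domains and the
#' domain amplitude on each plateau, with hyperbolic-tangent transitions.
#' Touching domains (zero gap) combine exactly into one longer plateau;
#' strictly overlapping domains must share the same amplitude and are
#' combined by taking the pointwise maximum of their bumps.
#'
#' @param s_grid Arclength sample positions \[nm\].
#' @param domains List of [domain_spec()] objects (possibly empty).
#' @param baseline Field value outside all domains.
#' @param deriv Derivative order with respect to arclength: 0 (the field),
#'   1, or 2. Derivatives are analytic, not finite differences.
#' @param L_total Total tube length used for the containment check; defaults
#'   to \code{max(s_grid)}.
#' @return Numeric vector of field samples (or its derivative).
#' @export
#' @examples
#' s <- seq(0, 2e4, length.out = 801)
#' dom <- domain_spec(center = 1e4, length = 8000, amplitude = 1.25e-4,
#'                    transition_width = 350)
#' sig <- tanh_profile(s, list(dom), baseline = 0)
#' max(sig)   # ~1.25e-4 at the plateau
tanh_profile <- function(s_grid, domains, baseline, deriv = 0L,
                         L_total = max(s_grid)) {
  deriv <- as.integer(deriv)
  stopifnot(deriv %in% 0:2)
  if (length(domains) == 0L)
    return(rep(if (deriv == 0L) baseline else 0, length(s_grid)))
  check_domains(domains, L_total)
  any_overlap <- FALSE
  if (length(domains) > 1L) {
    for (i in seq_len(length(domains) - 1L))
      for (j in seq(i + 1L, length(domains)))
        if (domains_overlap(domains[[i]], domains[[j]])) any_overlap <- TRUE
  }
  bumps <- vapply(domains,
                  function(d) (d$amplitude - baseline) *
                    domain_bump(s_grid, d, deriv),
                  numeric(length(s_grid)))
  bumps <- matrix(bumps, nrow = length(s_grid))
  total <- if (any_overlap) apply(bumps, 1L, max) else rowSums(bumps)
  if (deriv == 0L) baseline + total else total
}

# Assemble a profile_set from per-field domain lists. All evaluators are
# analytic closures so the solver can query sigma', sigma'', kappa_G''
# without finite-difference noise.
make_profile_set <- function(params, sigma_domains, kappa_domains,
                             kappaG_domains, kappaG_base, n_grid) {
  L <- params$Lc
  s <- seq(0, L, length.out = n_grid)
  f <- function(doms, base, d) {
    force(doms); force(base); force(d)
    function(ss) tanh_profile(ss, doms, base, deriv = d, L_total = L)
  }
  funs <- list(
    sigma    = f(sigma_domains, 0, 0L),
    dsigma   = f(sigma_domains, 0, 1L),
    d2sigma  = f(sigma_domains, 0, 2L),
    kappa    = f(kappa_domains, params$kappa, 0L),
    dkappa   = f(kappa_domains, params$kappa, 1L),
    kappaG   = f(kappaG_domains, kappaG_base, 0L),
    dkappaG  = f(kappaG_domains, kappaG_base, 1L),
    d2kappaG = f(kappaG_domains, kappaG_base, 2L)
  )
  meta <- lapply(sigma_domains, function(d)
    list(center = d$center, length = d$length, amplitude = d$amplitude,
         transition_width = d$transition_width))
  structure(list(
    s = s,
    sigma = funs$sigma(s),
    kappa = funs$kappa(s),
    kappaG = funs$kappaG(s),
    funs = funs,
    domain_meta = meta,
    L_total = L,
    kappaG_base = kappaG_base
  ), class = "profile_set")
}

default_width <- function(params, L_domain) min(10 * params$Rc, L_domain / 20)

# Baseline Gaussian modulus for the bare bilayer; only its *variation*
# enters the mechanics, so the value matters only when delta_kappaG != 0.
default_kappaG <- function(params) -0.9 * params$kappa

#' Heterogeneity fields for a single centred domain
#'
#' Builds protein-density, bending-rigidity and Gaussian-modulus fields that
#' share one centred domain of plateau length \code{L_domain}: the protein
#' density rises from 0 to \code{sigma0}, the rigidity from kappa to
#' \code{kappa_ratio * kappa}, and the Gaussian modulus from its bare value
#' to \code{(1 + delta_kappaG)} times it. Rigidity and Gaussian-modulus
#' heterogeneity follow the protein domain: if \code{sigma0 = 0} there are
#' no proteins, but a rigid domain is still built when explicitly requested
#' via \code{kappa_ratio > 1}.
#'
#' @param params A [model_parameters()] object.
#' @param sigma0 Plateau protein density \[nm^-2\], >= 0.
#' @param kappa_ratio Rigidity ratio of the domain to the bare membrane.
#' @param delta_kappaG Relative Gaussian-modulus contrast of the domain.
#' @param L_domain Plateau length of the domain \[nm\], default 8000.
#' @param transition_width tanh half-width \[nm\]; default
#'   \code{min(10 * Rc, L_domain / 20)}.
#' @param n_grid Number of arclength samples for the stored fields.
#' @return A \code{profile_set}: sampled fields plus analytic evaluators.
#' @export
#' @examples
#' ps <- single_domain_profiles(model_parameters(), sigma0 = 1.25e-4)
#' max(ps$sigma)
single_domain_profiles <- function(params, sigma0, kappa_ratio = 1,
                                   delta_kappaG = 0, L_domain = 8000,
                                   transition_width = NULL, n_grid = 2001) {
  stopifnot(inherits(params, "model_parameters"))
  if (sigma0 < 0) stop("sigma0 must be non-negative")
  if (L_domain >= params$Lc)
    stop("L_domain must be smaller than the tube length Lc")
  w <- if (is.null(transition_width)) default_width(params, L_domain)
       else transition_width
  ctr <- params$Lc / 2
  sd <- if (sigma0 > 0)
    list(domain_spec(ctr, L_domain, sigma0, w)) else list()
  kd <- if (kappa_ratio != 1)
    list(domain_spec(ctr, L_domain, kappa_ratio * params$kappa, w))
  else list()
  kG0 <- default_kappaG(params)
  gd <- if (delta_kappaG != 0)
    list(domain_spec(ctr, L_domain, (1 + delta_kappaG) * kG0, w)) else list()
  make_profile_set(params, sd, kd, gd, kG0, n_grid)
}

#' Heterogeneity fields for two identical symmetric domains
#'
#' Places two identical domains symmetrically about the tube midpoint with
#' an end-to-end (plateau edge to plateau edge) gap of
#' \code{L_separation}. With \code{L_separation = 0} the plateaus touch and
#' the field is exactly that of a single domain of length
#' \code{2 * L_domain}.
#'
#' @inheritParams single_domain_profiles
#' @param L_separation End-to-end gap between the two plateaus \[nm\].
#' @return A \code{profile_set}.
#' @export
two_domain_profiles <- function(params, sigma0, kappa_ratio = 1,
                                delta_kappaG = 0, L_domain = 8000,
                                L_separation = 4000,
                                transition_width = NULL, n_grid = 2001) {
  stopifnot(inherits(params, "model_parameters"))
  if (sigma0 < 0) stop("sigma0 must be non-negative")
  if (L_separation < 0) stop("L_separation must be non-negative")
  if (2 * L_domain + L_separation > params$Lc)
    stop("2 * L_domain + L_separation exceeds the tube length Lc")
  w <- if (is.null(transition_width)) default_width(params, L_domain)
       else transition_width
  c1 <- params$Lc / 2 - (L_separation + L_domain) / 2
  c2 <- params$Lc / 2 + (L_separation + L_domain) / 2
  mk <- function(amp) list(domain_spec(c1, L_domain, amp, w),
                           domain_spec(c2, L_domain, amp, w))
  sd <- if (sigma0 > 0) mk(sigma0) else list()
  kd <- if (kappa_ratio != 1) mk(kappa_ratio * params$kappa) else list()
  kG0 <- default_kappaG(params)
  gd <- if (delta_kappaG != 0) mk((1 + delta_kappaG) * kG0) else list()
  make_profile_set(params, sd, kd, gd, kG0, n_grid)
}

#' Fully homogeneous fields (bare tube)
#'
#' @inheritParams single_domain_profiles
#' @return A \code{profile_set} with sigma = 0 and uniform moduli.
#' @export
homogeneous_profiles <- function(params, n_grid = 2001) {
  make_profile_set(params, list(), list(), list(),
                   default_kappaG(params), n_grid)
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Heterogeneity profiles on [0, ", x$L_total, "] nm (",
      length(x$s), " samples)\n", sep = "")
  cat(sprintf("  sigma:   max %.4g nm^-2\n", max(x$sigma)))
  cat(sprintf("  kappa:   %.4g - %.4g pN nm\n", min(x$kappa), max(x$kappa)))
  cat(sprintf("  kappa_G: %.4g - %.4g pN nm\n", min(x$kappaG), max(x$kappaG)))
  if (length(x$domain_meta) > 0L) {
    for (d in x$domain_meta)
      cat(sprintf("  domain: center %.0f nm, length %.0f nm, amplitude %.4g, w %.0f nm\n",
                  d$center, d$length, d$amplitude, d$transition_width))
  } else cat("  (no protein domains)\n")
  invisible(x)
}

#' Export / import profile samples as CSV
#'
#' Columns: \code{s_nm, sigma_nm2, kappa_pNnm, kappaG_pNnm}. On re-import
#' the analytic evaluators are rebuilt as interpolating splines of the
#' samples, so derivative queries remain available (at spline accuracy).
#'
#' @param profiles A \code{profile_set}.
#' @param path CSV file path.
#' @return \code{path} (write) or a \code{profile_set} (read).
#' @export
write_profiles_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "profile_set"))
  utils::write.csv(data.frame(s_nm = profiles$s,
                              sigma_nm2 = profiles$sigma,
                              kappa_pNnm = profiles$kappa,
                              kappaG_pNnm = profiles$kappaG),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("s_nm", "sigma_nm2", "kappa_pNnm", "kappaG_pNnm")
  if (!all(need %in% names(d)))
    stop("profile CSV must have columns ", paste(need, collapse = ", "))
  sfun  <- stats::splinefun(d$s_nm, d$sigma_nm2, method = "natural")
  kfun  <- stats::splinefun(d$s_nm, d$kappa_pNnm, method = "natural")
  gfun  <- stats::splinefun(d$s_nm, d$kappaG_pNnm, method = "natural")
  funs <- list(
    sigma = function(s) sfun(s), dsigma = function(s) sfun(s, deriv = 1),
    d2sigma = function(s) sfun(s, deriv = 2),
    kappa = function(s) kfun(s), dkappa = function(s) kfun(s, deriv = 1),
    kappaG = function(s) gfun(s), dkappaG = function(s) gfun(s, deriv = 1),
    d2kappaG = function(s) gfun(s, deriv = 2)
  )
  structure(list(s = d$s_nm, sigma = d$sigma_nm2, kappa = d$kappa_pNnm,
                 kappaG = d$kappaG_pNnm, funs = funs, domain_meta = list(),
                 L_total = max(d$s_nm),
                 kappaG_base = d$kappaG_pNnm[1L]),
            class = "profile_set")
}
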