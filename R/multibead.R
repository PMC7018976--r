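#' Count beads on a solved shape
#'
#' Number of beads after saddle merging (see [measure_beads()]);
#' deterministic for a given shape and thresholds.
#'
#' @inheritParams measure_beads
#' @return Integer bead count (0 for a bare tube).
#' @export
count_beads <- function(shape, epsilon = 0.1, saddle_frac = 0.95) {
  nrow(measure_beads(shape, epsilon = epsilon, saddle_frac = saddle_frac,
                     classify = FALSE))
}

# Reach the equilibrium state of a two-domain tube at a given separation by
# staged continuation: rigidity ratio first (at low density), then density.
reach_two_domain_state <- function(params, sigma0, kappa_ratio, L_domain,
                                   separation, config,
                                   sigma_step = 2.5e-5) {
  sig_lo <- min(sigma0, 1e-5)
  guess <- NULL
  if (kappa_ratio != 1) {
    kr_path <- unique(c(seq(1, kappa_ratio, by = 2.5), kappa_ratio))
    br <- continuation(kr_path, function(v)
      list(fields = two_domain_profiles(params, sig_lo, v, L_domain = L_domain,
                                        L_separation = separation),
           params = params),
      config = config, param_name = "kappa_ratio")
    if (!br$converged[length(kr_path)])
      stop("rigidity staging failed at separation ", separation)
    guess <- br$shapes[[length(kr_path)]]
  }
  if (sigma0 > sig_lo) {
    ns <- max(1L, ceiling((sigma0 - sig_lo) / sigma_step))
    spath <- c(sig_lo, sig_lo + (sigma0 - sig_lo) * seq_len(ns) / ns)
    br <- continuation(spath, function(v)
      list(fields = two_domain_profiles(params, v, kappa_ratio,
                                        L_domain = L_domain,
                                        L_separation = separation),
           params = params),
      config = config, guess = guess, param_name = "sigma0")
    if (!br$converged[length(spath)])
      stop("density staging failed at separation ", separation)
    guess <- br$shapes[[length(spath)]]
  }
  if (is.null(guess)) {
    st <- two_domain_profiles(params, sigma0, kappa_ratio,
                              L_domain = L_domain,
                              L_separation = separation)
    guess <- solve_shape(st, params, config = config)
  }
  guess
}

#' Two-domain merge study: bead count versus domain separation
#'
#' Sweeps the end-to-end separation of two identical heterogeneous domains
#' by quasi-static continuation (each solve seeded from its neighbour) and
#' records the bead count, bead radius and total energy per separation.
#' The decreasing sweep starts from the largest separation, the increasing
#' sweep from the smallest. A snap-through transition is a discontinuity of
#' the quasi-static decreasing sweep: either the two-bead branch folds (no
#' nearby solution, so the sweep restarts on the one-bead branch) or the
#' radial profile jumps by more than ten times the typical step change.
#' With \code{direction = "both"} the hysteresis between the two sweeps
#' and the branch energy gap are also reported.
#'
#' @param params A [model_parameters()] object (use \code{phi = 0} for
#'   rigidity-only domains, i.e. C = 0).
#' @param sigma0 Plateau protein density \[nm^-2\].
#' @param kappa_ratio Rigidity ratio of the domains.
#' @param L_domain Plateau length of each domain \[nm\].
#' @param separations Separation grid \[nm\]; must satisfy
#'   2 L_domain + max(separation) <= Lc.
#' @param direction \code{"decreasing"}, \code{"increasing"} or
#'   \code{"both"}.
#' @param config A [solver_config()].
#' @return A \code{merge_study_result}: per-direction tables
#'   (separation, bead count, r_b, energy), the critical separation
#'   (largest separation whose decreasing-sweep state has a single bead),
#'   \code{transition_type} (\code{"smooth"} or \code{"snap_through"}),
#'   hysteresis width and the energy gap between branches at the
#'   transition.
#' @export
merge_study <- function(params, sigma0, kappa_ratio = 1, L_domain = 8000,
                        separations = seq(0, 4000, length.out = 21),
                        direction = c("both", "decreasing", "increasing"),
                        config = solver_config()) {
  direction <- match.arg(direction)
  separations <- sort(unique(separations))
  if (2 * L_domain + max(separations) > params$Lc)
    stop("separation grid exceeds the tube: 2*L_domain + max separation > Lc")

  # Staging at the sweep start can fail when the domains sit flush against
  # the clamped tube ends (largest separations); fall back to staging at a
  # smaller separation and walking the separation up as far as it converges.
  reach_start <- function(target) {
    st <- tryCatch(reach_two_domain_state(params, sigma0, kappa_ratio,
                                          L_domain, target, config),
                   error = function(e) NULL)
    if (!is.null(st)) return(list(shape = st, sep = target))
    for (frac in c(0.5, 0.25, 0.1)) {
      sep0 <- min(separations) + frac * (target - min(separations))
      st <- tryCatch(reach_two_domain_state(params, sigma0, kappa_ratio,
                                            L_domain, sep0, config),
                     error = function(e) NULL)
      if (is.null(st)) next
      ach <- sep0
      path0 <- separations[separations > sep0 & separations <= target]
      if (target < sep0) path0 <- rev(separations[separations < sep0 &
                                                    separations >= target])
      if (length(path0) > 0L) {
        br0 <- continuation(path0, function(v)
          list(fields = two_domain_profiles(params, sigma0, kappa_ratio,
                                            L_domain = L_domain,
                                            L_separation = v),
               params = params),
          config = config, guess = st, param_name = "L_separation")
        if (any(br0$converged)) {
          k <- max(which(br0$converged))
          st <- br0$shapes[[k]]
          ach <- path0[k]
        }
      }
      return(list(shape = st, sep = ach))
    }
    stop("could not reach a two-domain state near separation ", target)
  }

  setup_sep <- function(v)
    list(fields = two_domain_profiles(params, sigma0, kappa_ratio,
                                      L_domain = L_domain,
                                      L_separation = v),
         params = params)

  # One quasi-static sweep along `path`. When the tracked branch folds
  # (continuation truncates), the physical system snaps to the other
  # equilibrium branch; the sweep restarts there, seeded from the
  # companion sweep's shape at that separation (or a fresh staged solve),
  # and the restart point is flagged as a jump.
  run_sweep <- function(path, companion = NULL) {
    counts <- rep(NA_integer_, length(path))
    r_b <- rep(NA_real_, length(path)); en <- rep(NA_real_, length(path))
    jmp <- rep(FALSE, length(path)); conv <- rep(FALSE, length(path))
    shapes <- vector("list", length(path))
    start <- reach_start(path[1L])
    usable <- if (path[1L] >= path[length(path)]) which(path <= start$sep)
              else which(path >= start$sep)
    i <- usable[1L]
    guess <- start$shape
    restarted <- FALSE
    restart_at <- NA_integer_
    while (i <= length(path)) {
      seg <- path[i:length(path)]
      br <- continuation(seg, setup_sep, config = config, guess = guess,
                         param_name = "L_separation")
      for (k in which(br$converged)) {
        j <- i + k - 1L
        counts[j] <- count_beads(br$shapes[[k]])
        r_b[j] <- br$table$r_b_nm[k]
        en[j] <- br$table$energy_pNnm[k]
        jmp[j] <- br$table$jump[k]
        conv[j] <- TRUE
        shapes[[j]] <- br$shapes[[k]]
      }
      if (is.na(br$truncated_at)) break
      # branch fold: restart on the other branch at the failed point
      i <- i + br$truncated_at - 1L
      guess <- NULL
      if (!is.null(companion) && !is.null(companion$shapes[[match(path[i],
                                           companion$table$separation_nm)]]))
        guess <- companion$shapes[[match(path[i],
                                         companion$table$separation_nm)]]
      sol <- if (!is.null(guess)) {
        tryCatch(solve_shape(setup_sep(path[i])$fields, params,
                             guess = guess, config = config),
                 error = function(e) NULL)
      } else {
        tryCatch(reach_two_domain_state(params, sigma0, kappa_ratio,
                                        L_domain, path[i], config),
                 error = function(e) NULL)
      }
      if (is.null(sol) || restarted) break
      restarted <- TRUE
      restart_at <- i
      guess <- sol
    }
    if (restarted && conv[restart_at]) jmp[restart_at] <- TRUE
    list(shapes = shapes, restarted = restarted,
         table = data.frame(separation_nm = path, n_beads = counts,
                            r_b_nm = r_b, energy_pNnm = en,
                            jump = jmp, converged = conv))
  }

  # Re-examine an apparent shape jump on a 4x finer separation grid: a
  # smooth-but-fast merge resolves into proportionally smaller steps, a
  # true discontinuity persists.
  refine_jump <- function(sweep) {
    tb <- sweep$table
    jx <- which(tb$jump)
    if (length(jx) == 0L) return(FALSE)
    step <- mean(diff(separations))
    for (k in jx) {
      sep_j <- tb$separation_nm[k]
      hi <- sep_j + step
      ki <- which(abs(tb$separation_nm - hi) < 1e-9)
      if (length(ki) == 0L || !tb$converged[ki]) return(TRUE)
      fine <- seq(hi, max(0, sep_j - step), by = -step / 4)
      br <- continuation(fine, setup_sep, config = config,
                         guess = sweep$shapes[[ki]],
                         param_name = "L_separation")
      if (!is.na(br$truncated_at) || any(br$table$jump, na.rm = TRUE))
        return(TRUE)
    }
    FALSE
  }

  dec <- inc <- NULL
  if (direction %in% c("both", "increasing"))
    inc <- run_sweep(separations)
  if (direction %in% c("both", "decreasing"))
    dec <- run_sweep(rev(separations), companion = inc)

  ref <- if (!is.null(dec)) dec else inc
  tab <- ref$table[order(ref$table$separation_nm), ]
  one <- tab$separation_nm[!is.na(tab$n_beads) & tab$n_beads == 1L]
  critical <- if (length(one) > 0L) max(one) else NA_real_
  unresolved <- is.na(critical) ||
    (length(one) > 0L && max(one) == max(separations))

  # Snap-through = discontinuity of the quasi-static decreasing sweep: the
  # two-bead branch folds (forcing a restart on the one-bead branch) or the
  # shape jumps discontinuously between neighbouring separations. The
  # hysteresis of the two sweep directions is reported alongside; it is not
  # used for classification because upward continuation follows the
  # metastable single-bead branch far beyond its physical relevance.
  snap <- FALSE
  energy_gap <- 0
  primary <- if (!is.null(dec)) dec else inc
  if (primary$restarted) {
    snap <- TRUE
  } else if (any(primary$table$jump, na.rm = TRUE)) {
    snap <- refine_jump(primary)
  }
  if (snap && any(primary$table$jump, na.rm = TRUE)) {
    tb <- primary$table[order(primary$table$separation_nm), ]
    jx <- which(tb$jump)
    for (k in jx) {
      lo <- if (k > 1L) tb$energy_pNnm[k - 1L] else NA
      hi <- if (k < nrow(tb)) tb$energy_pNnm[k + 1L] else NA
      nb <- c(lo, hi)
      nb <- nb[!is.na(nb)]
      if (length(nb) > 0L && !is.na(tb$energy_pNnm[k]))
        energy_gap <- max(energy_gap, abs(tb$energy_pNnm[k] - nb))
    }
  }
  hysteresis <- 0
  if (!is.null(dec) && !is.null(inc)) {
    d <- dec$table[order(dec$table$separation_nm), ]
    u <- inc$table
    both_ok <- !is.na(d$n_beads) & !is.na(u$n_beads)
    disagree <- both_ok & d$n_beads != u$n_beads
    if (any(disagree)) {
      hysteresis <- diff(range(d$separation_nm[disagree])) +
        mean(diff(separations))
      energy_gap <- max(energy_gap,
                        abs(d$energy_pNnm[disagree] -
                              u$energy_pNnm[disagree]))
    }
  }

  structure(list(
    separations = separations,
    decreasing = if (!is.null(dec)) dec$table else NULL,
    increasing = if (!is.null(inc)) inc$table else NULL,
    shapes_decreasing = if (!is.null(dec)) dec$shapes else NULL,
    shapes_increasing = if (!is.null(inc)) inc$shapes else NULL,
    critical_separation = critical,
    critical_unresolved = unresolved,
    transition_type = if (snap) "snap_through" else "smooth",
    hysteresis_width = hysteresis,
    energy_gap = energy_gap,
    sigma0 = sigma0, kappa_ratio = kappa_ratio, L_domain = L_domain
  ), class = "merge_study_result")
}

#' @export
print.merge_study_result <- function(x, ...) {
  cat("Two-domain merge study (sigma0 =", format(x$sigma0, digits = 3),
      "nm^-2, kappa_ratio =", x$kappa_ratio, ")\n")
  cat("  critical separation:",
      if (is.na(x$critical_separation)) "unresolved"
      else paste0(format(x$critical_separation, digits = 4), " nm",
                  if (x$critical_unresolved) " (at grid edge)" else ""),
      "\n")
  cat("  transition:", x$transition_type)
  if (x$transition_type == "snap_through")
    cat(" (hysteresis width ", format(x$hysteresis_width, digits = 3),
        " nm, energy gap ", format(x$energy_gap, digits = 4), " pN nm)",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Check the geometric merge criterion
#'
#' Two beads merge into one roughly when their separation falls below the
#' bead diameter. Returns TRUE when the measured critical separation
#' agrees with 2 * r_b (the bead radius at large separation) to within one
#' separation-grid step; NA (indeterminate) when the study did not resolve
#' the transition inside its grid.
#'
#' @param result A \code{merge_study_result}.
#' @param r_b_far Bead radius at large separation \[nm\].
#' @return TRUE, FALSE, or NA (indeterminate).
#' @export
merge_criterion_check <- function(result, r_b_far) {
  stopifnot(inherits(result, "merge_study_result"))
  if (is.na(result$critical_separation) || result$critical_unresolved)
    return(NA)
  step <- mean(diff(result$separations))
  abs(result$critical_separation - 2 * r_b_far) <= step
}

#' Export a merge study as CSV
#'
#' Long format with a \code{direction} column
#' (\code{separation_nm, n_beads, r_b_nm, energy_pNnm, direction}).
#'
#' @param result A \code{merge_study_result}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_merge_study_csv <- function(result, path) {
  rows <- list()
  if (!is.null(result$decreasing)) {
    d <- result$decreasing; d$direction <- "decreasing"; rows <- c(rows, list(d))
  }
  if (!is.null(result$increasing)) {
    d <- result$increasing; d$direction <- "increasing"; rows <- c(rows, list(d))
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out[, c("separation_nm", "n_beads", "r_b_nm",
                           "energy_pNnm", "direction")],
                   path, row.names = FALSE)
  invisible(path)
}
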