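#' Detect and measure beads on a solved shape
#'
#' A bead is a maximal contiguous region where the radius exceeds
#' \code{(1 + epsilon)} times the nominal tube radius. Within a region,
#' local maxima separated only by a shallow saddle (saddle radius above
#' \code{saddle_frac} times the smaller peak) are merged into one bead.
#' Each bead reports its radius (max r), the arclength of the maximum, and
#' the radial variation over the centre of its plateau (the contiguous
#' sub-region with r above \code{plateau_frac * r_b}; the variation is
#' taken over the middle half of that sub-region so the 10-percent
#' shoulders of a genuinely flat-topped bead do not mask its flatness).
#'
#' @param shape A converged \code{membrane_shape}.
#' @param fields Unused; accepted for call-site symmetry.
#' @param epsilon Detection threshold as a fraction above Rc (default 0.1).
#' @param plateau_frac Plateau definition as a fraction of r_b (default 0.9).
#' @param saddle_frac Saddle-merging threshold (default 0.95).
#' @param classify Logical; fill the \code{shape_class} column via
#'   [classify_bead()].
#' @return A data frame of class \code{"bead_measurement"} with one row per
#'   bead: \code{r_b}, \code{position}, \code{plateau_variation},
#'   \code{shape_class} and the index range of the bead region. Zero rows
#'   for a bare tube.
#' @export
measure_beads <- function(shape, fields = NULL, epsilon = 0.1,
                          plateau_frac = 0.9, saddle_frac = 0.95,
                          classify = TRUE) {
  stopifnot(inherits(shape, "membrane_shape"))
  Rc <- shape$params$Rc
  thr <- (1 + epsilon) * Rc
  above <- shape$r > thr
  empty <- data.frame(r_b = numeric(0), position = numeric(0),
                      plateau_variation = numeric(0),
                      shape_class = character(0),
                      i_start = integer(0), i_end = integer(0),
                      i_peak = integer(0))
  class(empty) <- c("bead_measurement", "data.frame")
  if (!any(above)) return(empty)

  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  regions <- cbind(starts, ends)[rl$values, , drop = FALSE]

  rows <- list()
  for (k in seq_len(nrow(regions))) {
    i0 <- regions[k, 1L]; i1 <- regions[k, 2L]
    rr <- shape$r[i0:i1]
    n <- length(rr)
    # local maxima inside the region (plateau-safe)
    if (n < 3L) {
      peaks <- which.max(rr)
    } else {
      peaks <- which(diff(sign(diff(rr))) < 0) + 1L
      if (length(peaks) == 0L) peaks <- which.max(rr)
    }
    # merge peaks separated by shallow saddles
    peaks <- sort(peaks)
    merged <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- merged[length(merged)]
      saddle <- min(rr[last:p])
      if (saddle > saddle_frac * min(rr[last], rr[p])) {
        if (rr[p] > rr[last]) merged[length(merged)] <- p
      } else merged <- c(merged, p)
    }
    # split the region at the deepest saddle between retained peaks
    bounds <- c(1L, vapply(seq_len(length(merged) - 1L), function(q) {
      seg <- merged[q]:merged[q + 1L]
      seg[which.min(rr[seg])]
    }, integer(1)), n)
    for (q in seq_along(merged)) {
      j0 <- bounds[q]; j1 <- bounds[q + 1L]
      sub <- rr[j0:j1]
      pk <- j0 + which.max(sub) - 1L
      r_b <- rr[pk]
      # plateau: contiguous run around the peak with r > plateau_frac * r_b
      pl <- which(sub >= plateau_frac * r_b)
      pkrel <- pk - j0 + 1L
      lo <- pkrel; while (lo - 1L >= 1L && (lo - 1L) %in% pl) lo <- lo - 1L
      hi <- pkrel; while (hi + 1L <= length(sub) && (hi + 1L) %in% pl) hi <- hi + 1L
      qlen <- hi - lo + 1L
      c0 <- lo + floor(qlen / 4); c1 <- hi - floor(qlen / 4)
      core <- sub[c0:c1]
      rows[[length(rows) + 1L]] <- data.frame(
        r_b = r_b,
        position = shape$s[i0 + pk - 1L],
        plateau_variation = (max(core) - min(core)) / r_b,
        shape_class = NA_character_,
        i_start = i0 + j0 - 1L, i_end = i0 + j1 - 1L,
        i_peak = i0 + pk - 1L)
    }
  }
  out <- do.call(rbind, rows)
  if (classify) {
    for (k in seq_len(nrow(out)))
      out$shape_class[k] <- classify_bead(shape, out[k, , drop = FALSE])
  }
  class(out) <- c("bead_measurement", "data.frame")
  out
}

running_mean <- function(v, window) {
  if (window <= 1L) return(v)
  kern <- rep(1 / window, window)
  out <- stats::filter(v, kern, sides = 2)
  out[is.na(out)] <- v[is.na(out)]
  as.numeric(out)
}

#' Classify a bead as ellipsoidal, cylindrical or unduloid
#'
#' Cylindrical beads are flat-topped: the radial variation over the bead
#' plateau is below 1 percent. Otherwise the sign of H'' (second arclength
#' derivative of the mean curvature, smoothed finite differences on the
#' solution mesh) over the bead interior decides: positive everywhere
#' means an ellipsoidal dome; a sign change means an unduloid-like
#' neck-and-bulge profile.
#'
#' @param shape A converged \code{membrane_shape}.
#' @param bead One row of [measure_beads()] output.
#' @param window Smoothing window (mesh points) applied to H before
#'   differencing.
#' @param rel_tol Curvature derivatives below this fraction of the maximum
#'   are treated as zero when looking for sign changes.
#' @return One of \code{"cylindrical"}, \code{"ellipsoidal"},
#'   \code{"unduloid"}.
#' @export
classify_bead <- function(shape, bead, window = 5L, rel_tol = 0.05) {
  stopifnot(inherits(shape, "membrane_shape"))
  if (!isTRUE(shape$converged))
    stop("cannot classify a bead on an unconverged shape")
  if (bead$plateau_variation < 0.01) return("cylindrical")
  i0 <- bead$i_start; i1 <- bead$i_end
  idx <- i0:i1
  Hs <- running_mean(shape$H[idx], window)
  s <- shape$s[idx]
  n <- length(idx)
  if (n < 2L * window + 5L) return("ellipsoidal")
  d1 <- function(v) {
    out <- numeric(n)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
    out[1] <- out[2]; out[n] <- out[n - 1]
    out
  }
  d2 <- d1(d1(Hs))[2:(n - 1)]
  # drop smoothing-contaminated edges
  pad <- max(window, 3L)
  d2 <- d2[(pad + 1L):(length(d2) - pad)]
  if (length(d2) == 0L) return("ellipsoidal")
  sig <- d2[abs(d2) > rel_tol * max(abs(d2))]
  if (length(sig) > 0L && any(sig > 0) && any(sig < 0)) "unduloid"
  else "ellipsoidal"
}

class_order <- c(none = 0L, ellipsoidal = 1L, cylindrical = 2L,
                 unduloid = 3L)

#' Bead-morphology phase diagram
#'
#' Classifies the equilibrium bead over a grid of protein density and
#' rigidity ratio (both heterogeneities share the centred domain). Each
#' rigidity-ratio column is reached by continuation: first in kappa_ratio
#' at the smallest nonzero density, then upward in density through the
#' requested values. Cells with sigma0 = 0 have no protein and hence no
#' heterogeneous domain at all; they are classified \code{"none"}.
#' Unconverged cells are marked \code{NA}, not interpolated. Each cell also
#' records log10 of the ratio of the protein-induced and rigidity-induced
#' length scales (evaluated at the edge tension).
#'
#' @param sigma0_values Increasing protein densities \[nm^-2\] (may start
#'   at 0).
#' @param kappa_ratio_values Rigidity ratios (>= 1).
#' @param params A [model_parameters()] object.
#' @param config A [solver_config()].
#' @param L_domain Domain plateau length \[nm\].
#' @param sigma_step Maximum continuation step in sigma0 \[nm^-2\];
#'   requested values further apart are bridged by inserted steps.
#' @return A \code{phase_diagram} object: the axis grids, a class map and a
#'   log-ratio map (matrices, sigma0 x kappa_ratio), and a long-format
#'   data frame \code{table}.
#' @export
phase_diagram <- function(sigma0_values, kappa_ratio_values,
                          params = model_parameters(),
                          config = solver_config(),
                          L_domain = 8000, sigma_step = 2.5e-5) {
  sigma0_values <- sort(sigma0_values)
  nclass <- matrix(NA_character_, nrow = length(sigma0_values),
                   ncol = length(kappa_ratio_values),
                   dimnames = list(NULL, NULL))
  rbmap <- matrix(NA_real_, nrow = length(sigma0_values),
                  ncol = length(kappa_ratio_values))
  logmap <- outer(sigma0_values, kappa_ratio_values,
                  function(sg, kr) {
                    mapply(function(a, b)
                      induced_length_scales(a, params$lambda0,
                                            b * params$kappa, params)$log_ratio,
                      sg, kr)
                  })
  pos <- sigma0_values[sigma0_values > 0]
  # cells beyond the solution branch fail; bound the bisection effort
  config <- do.call(solver_config,
                    utils::modifyList(unclass(config),
                                      list(step_halving_limit =
                                             min(config$step_halving_limit, 4L))))
  for (j in seq_along(kappa_ratio_values)) {
    kr <- kappa_ratio_values[j]
    nclass[sigma0_values == 0, j] <- "none"
    if (length(pos) == 0L) next
    # stage 1: grow the rigidity contrast at a low density
    sig_lo <- min(1e-5, pos[1L])
    kr_path <- unique(c(seq(1, kr, by = 2.5), kr))
    seed <- continuation(kr_path, function(v) {
      list(fields = single_domain_profiles(params, sig_lo, v,
                                           L_domain = L_domain),
           params = params)
    }, config = config, param_name = "kappa_ratio")
    guess <- if (any(seed$converged))
      seed$shapes[[max(which(seed$converged))]] else NULL
    if (is.null(guess) || !seed$converged[length(kr_path)]) next
    # stage 2: sweep the density upward through the requested values
    spath <- sig_lo
    for (v in pos[pos > sig_lo]) {
      gap <- v - spath[length(spath)]
      if (gap > sigma_step)
        spath <- c(spath, spath[length(spath)] +
                     seq_len(ceiling(gap / sigma_step) - 1L) *
                     gap / ceiling(gap / sigma_step))
      spath <- c(spath, v)
    }
    br <- continuation(spath, function(v) {
      list(fields = single_domain_profiles(params, v, kr,
                                           L_domain = L_domain),
           params = params)
    }, config = config, guess = guess, param_name = "sigma0")
    for (i in seq_along(pos)) {
      k <- which(abs(spath - pos[i]) < 1e-15)[1L]
      row <- which(sigma0_values == pos[i])
      if (br$converged[k]) {
        beads <- measure_beads(br$shapes[[k]])
        if (nrow(beads) == 0L) {
          nclass[row, j] <- "none"
        } else {
          main <- which.max(beads$r_b)
          nclass[row, j] <- beads$shape_class[main]
          rbmap[row, j] <- beads$r_b[main]
        }
      }
    }
  }
  tab <- expand.grid(sigma0 = sigma0_values,
                     kappa_ratio = kappa_ratio_values)
  tab$shape_class <- as.vector(nclass)
  tab$log_ratio <- as.vector(logmap)
  tab$r_b_nm <- as.vector(rbmap)
  structure(list(sigma0 = sigma0_values,
                 kappa_ratio = kappa_ratio_values,
                 class_map = nclass, log_ratio_map = logmap,
                 r_b_map = rbmap, table = tab,
                 lambda0 = params$lambda0),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("Bead-morphology phase diagram (lambda0 =", x$lambda0, "pN/nm)\n")
  m <- x$class_map
  abbrev <- c(none = ".", ellipsoidal = "E", cylindrical = "C",
              unduloid = "U")
  disp <- matrix(ifelse(is.na(m), "?", abbrev[m]), nrow = nrow(m))
  rownames(disp) <- format(x$sigma0, digits = 3)
  colnames(disp) <- format(x$kappa_ratio, digits = 3)
  print(disp, quote = FALSE)
  cat("rows: sigma0 [nm^-2]; cols: kappa_ratio;",
      "E/C/U = ellipsoidal/cylindrical/unduloid\n")
  invisible(x)
}

#' Export a phase diagram as long-format CSV
#'
#' Columns: \code{sigma0, kappa_ratio, shape_class, log_ratio, r_b_nm}.
#' @param pd A \code{phase_diagram}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phase_diagram_csv <- function(pd, path) {
  utils::write.csv(pd$table, path, row.names = FALSE)
  invisible(path)
}
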