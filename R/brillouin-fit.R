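# Damped-harmonic-oscillator (DHO) analysis of Brillouin spectra.
#
# Protocol: (1) fit the Stokes and anti-Stokes peaks separately to verify
# their symmetry about the elastic line, (2) if asymmetric, rigidly shift
# the frequency axis to restore symmetry, (3) fit one DHO to the whole
# (two-sided) spectrum and use its parameters downstream.

# Spectral DHO evaluated at both signs of nu; gamma is the full linewidth.
.dho <- function(nu, omega, gamma, amplitude) {
  amplitude * gamma * omega^2 / ((nu^2 - omega^2)^2 + (gamma * nu)^2)
}

.half_prominence_width <- function(x, y, ipk, floor_level) {
  half <- floor_level + (y[ipk] - floor_level) / 2
  left <- ipk
  while (left > 1 && y[left] > half) left <- left - 1
  right <- ipk
  while (right < length(y) && y[right] > half) right <- right + 1
  w <- x[right] - x[left]
  if (w <= 0) w <- 2 * stats::median(diff(x))
  w
}

.side_grid_peak <- function(x, y, prominence_factor) {
  floor_level <- stats::median(y)
  noise <- stats::mad(diff(y)) / sqrt(2)
  ipk <- which.max(y)
  prom <- y[ipk] - floor_level
  if (prom < prominence_factor * max(noise, .Machine$double.eps)) {
    return(NULL)
  }
  list(pos = x[ipk], height = y[ipk], floor = floor_level, prom = prom,
       width = .half_prominence_width(x, y, ipk, floor_level))
}

# One-sided DHO fit with a free axis-shift delta: the data on this side are
# modelled as B + DHO(nu - delta; omega, gamma, A). Because the DHO is not a
# translation family, omega and delta are jointly identifiable from a single
# side; the shift of a miscalibrated axis lands in delta.
.fit_side <- function(x, y, grid_peak) {
  om0 <- abs(grid_peak$pos)
  start <- c(omega = om0, gamma = max(grid_peak$width, 0.05),
             amplitude = grid_peak$prom * max(grid_peak$width, 0.05),
             background = max(grid_peak$floor, 0), delta = 0)
  resid_fn <- function(p) {
    y - (p["background"] + .dho(x - p["delta"], p["omega"], p["gamma"],
                                p["amplitude"]))
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(omega = 0.5, gamma = 0.01, amplitude = 0, background = 0,
              delta = -1), upper = c(Inf, Inf, Inf, Inf, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  as.list(stats::coef(fit))
}

#' Locate the Stokes and anti-Stokes Brillouin peaks
#'
#' Finds the most prominent peak on each side of the elastic line (outside
#' the exclusion window) and refines each with a one-sided DHO fit carrying
#' a free axis-shift term. The reported peak positions are the DHO
#' frequencies offset by the fitted shift, so a rigid miscalibration of the
#' axis appears as a nonzero asymmetry `nu_stokes + nu_antistokes`.
#'
#' @param spec a brillouin [spectrum] spanning negative and positive
#'   frequencies.
#' @param exclusion half-width of the elastic-line exclusion window in GHz
#'   (default 2): points with `|nu| < exclusion` are ignored.
#' @param prominence_factor required peak prominence as a multiple of the
#'   robust noise level (default 5).
#' @return a list of class `peak_pair` with `nu_stokes`, `nu_antistokes`,
#'   `asymmetry` and the per-side fit parameters.
#' @export
locate_peaks <- function(spec, exclusion = 2, prominence_factor = 5) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$kind != "brillouin") {
    stop("locate_peaks expects a brillouin spectrum", call. = FALSE)
  }
  pos <- spec$axis >= exclusion
  neg <- spec$axis <= -exclusion
  if (sum(pos) < 8 || sum(neg) < 8) {
    stop("spectrum must cover both signs of frequency outside the ",
         "elastic-line exclusion window", call. = FALSE)
  }
  gp_s <- .side_grid_peak(spec$axis[pos], spec$intensity[pos],
                          prominence_factor)
  gp_a <- .side_grid_peak(spec$axis[neg], spec$intensity[neg],
                          prominence_factor)
  if (is.null(gp_s) || is.null(gp_a)) {
    stop("no peak with sufficient prominence on one or both sides ",
         "(empty or turbid acquisition?)", call. = FALSE)
  }
  fs <- .fit_side(spec$axis[pos], spec$intensity[pos], gp_s)
  fa <- .fit_side(spec$axis[neg], spec$intensity[neg], gp_a)
  nu_stokes <- fs$delta + fs$omega
  nu_antistokes <- fa$delta - fa$omega
  structure(list(nu_stokes = nu_stokes, nu_antistokes = nu_antistokes,
                 asymmetry = nu_stokes + nu_antistokes,
                 stokes_fit = fs, antistokes_fit = fa),
            class = "peak_pair")
}

#' Recenter a Brillouin axis onto the elastic line
#'
#' Shifts the frequency axis by half the Stokes/anti-Stokes asymmetry so
#' that the two peaks are symmetric about zero.
#'
#' @param spec a brillouin [spectrum].
#' @param pair a `peak_pair` from [locate_peaks()]; located automatically
#'   when missing.
#' @param tolerance residual asymmetry accepted after recentering, GHz
#'   (default 0.01).
#' @param max_offset largest credible drift, GHz (default 0.5); a larger
#'   apparent offset signals gross miscalibration and is an error.
#' @param ... passed to [locate_peaks()].
#' @return list with `spectrum` (recentered) and `offset` (GHz).
#' @export
recenter_axis <- function(spec, pair = NULL, tolerance = 0.01,
                          max_offset = 0.5, ...) {
  if (is.null(pair)) pair <- locate_peaks(spec, ...)
  offset <- pair$asymmetry / 2
  if (abs(offset) > max_offset) {
    stop(sprintf("axis offset %.3f GHz exceeds max_offset = %.3f GHz: ",
                 offset, max_offset),
         "gross frequency miscalibration, not drift", call. = FALSE)
  }
  out <- spec
  out$axis <- spec$axis - offset
  check <- locate_peaks(out, ...)
  if (abs(check$asymmetry) >= tolerance) {
    warning(sprintf(
      "residual asymmetry %.4f GHz after recentering (tolerance %.4f)",
      check$asymmetry, tolerance))
  }
  list(spectrum = out, offset = offset)
}

.dhofit_obj <- function(par, se, rss, n_points, converged, offset = 0) {
  structure(list(omega_b = par[["omega"]], gamma = par[["gamma"]],
                 amplitude = par[["amplitude"]],
                 background = par[["background"]],
                 recenter_offset = offset, rss = rss,
                 se_omega = se[["omega"]], se_gamma = se[["gamma"]],
                 converged = converged, n_points = n_points),
            class = "dho_fit")
}

#' @export
print.dho_fit <- function(x, ...) {
  cat(sprintf(
    "<DHO fit> omega_B = %.4f +/- %.4f GHz, Gamma = %.4f +/- %.4f GHz\n",
    x$omega_b, x$se_omega, x$gamma, x$se_gamma))
  cat(sprintf("  amplitude %.3g, background %.3g, rss %.3g, offset %.4f GHz%s\n",
              x$amplitude, x$background, x$rss, x$recenter_offset,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Fit a single DHO to a recentered Brillouin spectrum
#'
#' Fits the model
#' \deqn{I(\nu) = B + A \Gamma \omega_B^2 /
#'   ((\nu^2-\omega_B^2)^2 + (\Gamma\nu)^2)}
#' to all points outside the elastic-line exclusion window; the model is
#' even in \eqn{\nu}, so one parameter set fits the Stokes and anti-Stokes
#' peaks simultaneously. Standard errors come from the residual covariance
#' of the trust-region least-squares fit. On non-convergence the fit is
#' retried from seeded random perturbations of the start.
#'
#' @param spec a recentered brillouin [spectrum].
#' @param init optional named list/vector seeding `omega`, `gamma`,
#'   `amplitude`, `background`; derived from [locate_peaks()] when missing.
#' @param exclusion elastic-line exclusion half-width, GHz.
#' @param max_iter maximum optimizer iterations.
#' @param n_restarts random restarts attempted on non-convergence.
#' @param restart_seed seed for the restart perturbations.
#' @return an object of class `dho_fit`.
#' @export
fit_dho <- function(spec, init = NULL, exclusion = 2, max_iter = 200,
                    n_restarts = 3, restart_seed = 1L) {
  stopifnot(inherits(spec, "spectrum"))
  keep <- abs(spec$axis) >= exclusion
  x <- spec$axis[keep]
  y <- spec$intensity[keep]
  if (length(x) < 8) stop("too few points outside the exclusion window",
                          call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("constant spectrum: no Brillouin peak to fit", call. = FALSE)
  }
  if (is.null(init)) {
    pair <- locate_peaks(spec, exclusion = exclusion)
    fs <- pair$stokes_fit
    fa <- pair$antistokes_fit
    start <- c(omega = (pair$nu_stokes - pair$nu_antistokes) / 2,
               gamma = (fs$gamma + fa$gamma) / 2,
               amplitude = (fs$amplitude + fa$amplitude) / 2,
               background = max((fs$background + fa$background) / 2, 0))
  } else {
    init <- unlist(init)
    start <- c(omega = init[["omega"]], gamma = init[["gamma"]],
               amplitude = init[["amplitude"]],
               background = init[["background"]])
  }
  lower <- c(omega = 0.5, gamma = 0.01, amplitude = 0, background = 0)
  run <- function(p0) {
    minpack.lm::nls.lm(
      par = p0,
      fn = function(p) y - (p["background"] +
                              .dho(x, p["omega"], p["gamma"], p["amplitude"])),
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = 1e-12, ptol = 1e-12))
  }
  fit <- run(start)
  converged <- fit$info %in% 1:4
  if (!converged && n_restarts > 0) {
    rng <- .seeded_rng(restart_seed)
    for (k in seq_len(n_restarts)) {
      jitter <- exp(stats::rnorm(4, 0, 0.2))
      cand <- run(start * jitter)
      if (cand$info %in% 1:4 && cand$deviance < fit$deviance) {
        fit <- cand
        converged <- TRUE
        break
      }
    }
    rng$restore()
  }
  if (!converged) {
    stop("DHO fit failed to converge; last iterate: ",
         paste(sprintf("%s=%.4g", names(stats::coef(fit)), stats::coef(fit)),
               collapse = ", "), call. = FALSE)
  }
  par <- stats::coef(fit)
  if (par[["gamma"]] <= lower[["gamma"]] * 1.001) {
    warning("gamma collapsed to its lower bound: degenerate linewidth")
  }
  if (par[["omega"]] <= par[["gamma"]] / 4) {
    warning("omega_b <= gamma/4: peak not resolvable")
  }
  dof <- max(length(y) - length(par), 1)
  sigma2 <- fit$deviance / dof
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) {
    c(omega = NA_real_, gamma = NA_real_)
  } else {
    sqrt(pmax(diag(covm), 0))[c("omega", "gamma")]
  }
  .dhofit_obj(par, se, fit$deviance, length(y), TRUE)
}

#' Full Brillouin protocol: locate, recenter, single-DHO fit
#'
#' @inheritParams fit_dho
#' @param ... passed to [recenter_axis()].
#' @return a `dho_fit` whose `recenter_offset` records the applied axis
#'   shift.
#' @export
fit_brillouin <- function(spec, exclusion = 2, ...) {
  pair <- locate_peaks(spec, exclusion = exclusion)
  rc <- recenter_axis(spec, pair, ...)
  fit <- fit_dho(rc$spectrum, exclusion = exclusion)
  fit$recenter_offset <- rc$offset
  fit
}

#' Normalize fitted Brillouin shifts to condition controls
#'
#' Divides each fitted shift by the mean shift of the control samples in the
#' same normalization group (by default, acquisitions with the same
#' objective), mirroring per-panel normalization of batched measurements.
#'
#' @param omega_b numeric vector of fitted shifts (GHz).
#' @param condition character vector of condition labels.
#' @param group optional batching factor (e.g. objective); a single group
#'   when missing.
#' @param control label of the reference condition (default "control").
#' @return numeric vector of normalized shifts (dimensionless).
#' @export
normalize_to_controls <- function(omega_b, condition, group = NULL,
                                  control = "control") {
  if (is.null(group)) group <- rep("all", length(omega_b))
  stopifnot(length(omega_b) == length(condition),
            length(group) == length(omega_b))
  out <- rep(NA_real_, length(omega_b))
  for (g in unique(group)) {
    sel <- group == g
    ctrl <- omega_b[sel & condition == control]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) == 0) {
      stop("no control samples in normalization group '", g, "'",
           call. = FALSE)
    }
    out[sel] <- omega_b[sel] / mean(ctrl)
  }
  out
}
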