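# High-wavenumber Raman processing: fluorescence baseline removal,
# chip (PDMS) and medium reference subtraction, and the CH/OH band-area
# ratio that quantifies relative dry-mass vs water content.

#' CH and OH integration windows
#'
#' The high-wavenumber region is partitioned into a CH stretching window
#' (organic dry mass, band centered near 2900 cm^-1) and an OH stretching
#' window (water, centered near 3300 cm^-1). Defaults split at 3020 cm^-1.
#'
#' @param ch numeric length-2, CH window in cm^-1 (default c(2800, 3020)).
#' @param oh numeric length-2, OH window in cm^-1 (default c(3020, 3700)).
#' @return list of class `band_windows`.
#' @export
band_windows <- function(ch = c(2800, 3020), oh = c(3020, 3700)) {
  stopifnot(length(ch) == 2, length(oh) == 2, ch[1] < ch[2], oh[1] < oh[2])
  if (ch[2] > oh[1]) {
    stop("CH window must end at or before the OH window starts",
         call. = FALSE)
  }
  structure(list(ch = as.numeric(ch), oh = as.numeric(oh)),
            class = "band_windows")
}

#' Bundle the three Raman reference spectra
#'
#' @param pdms spectrum acquired on an empty PDMS chip (chip signature).
#' @param medium spectrum of the cell culture medium; carries only the OH
#'   band.
#' @param offchip reference spectrum of a spheroid acquired outside the
#'   chip (contamination-free).
#' @return list of class `raman_references`.
#' @export
raman_references <- function(pdms, medium, offchip) {
  for (s in list(pdms, medium, offchip)) {
    stopifnot(inherits(s, "spectrum"))
    if (s$kind != "raman") stop("references must be raman spectra",
                                call. = FALSE)
  }
  structure(list(pdms = pdms, medium = medium, offchip = offchip),
            class = "raman_references")
}

#' Resample a spectrum onto a target axis
#'
#' Linear interpolation; extrapolation outside the source span is refused.
#'
#' @param spec a [spectrum].
#' @param axis target axis, strictly increasing, within the source span.
#' @return resampled [spectrum].
#' @export
resample_to <- function(spec, axis) {
  stopifnot(inherits(spec, "spectrum"))
  axis <- as.numeric(axis)
  if (min(axis) < min(spec$axis) || max(axis) > max(spec$axis)) {
    stop("target axis extends outside the source span: extrapolation ",
         "refused", call. = FALSE)
  }
  yi <- stats::approx(spec$axis, spec$intensity, xout = axis)$y
  spectrum(axis, yi, kind = spec$kind, meta = spec$meta,
           min_points = min(16L, length(axis)))
}

#' Remove the laser-induced fluorescence baseline
#'
#' Fits a cubic smoothing spline through band-free anchor regions on either
#' side of the CH/OH complex and subtracts its prediction over the full
#' axis. The spline's effective degrees of freedom follow the knot spacing.
#'
#' @param spec a raman [spectrum].
#' @param knot_spacing approximate spacing of spline knots, cm^-1
#'   (default 50).
#' @param anchor_regions list of `c(lo, hi)` windows assumed band-free
#'   (defaults 2600-2750 and 3750-3900 cm^-1).
#' @param windows optional [band_windows]; anchors overlapping them are a
#'   configuration error.
#' @return list with `corrected` (baseline-subtracted spectrum), `baseline`
#'   (the fitted baseline as a spectrum) and `baseline_rss` (residual sum of
#'   squares over the anchor points).
#' @export
remove_baseline <- function(spec, knot_spacing = 50,
                            anchor_regions = list(c(2600, 2750),
                                                  c(3750, 3900)),
                            windows = NULL) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.null(windows)) {
    for (a in anchor_regions) {
      if (a[1] < windows$oh[2] && a[2] > windows$ch[1]) {
        stop("anchor region [", a[1], ", ", a[2],
             "] overlaps the band windows", call. = FALSE)
      }
    }
  }
  in_anchor <- rep(FALSE, length(spec$axis))
  span <- 0
  for (a in anchor_regions) {
    if (a[1] < min(spec$axis) || a[2] > max(spec$axis)) {
      stop("anchor region [", a[1], ", ", a[2],
           "] outside the spectral axis", call. = FALSE)
    }
    sel <- spec$axis >= a[1] & spec$axis <= a[2]
    if (sum(sel) < 3) {
      stop("anchor region [", a[1], ", ", a[2],
           "] covers fewer than 3 points", call. = FALSE)
    }
    in_anchor <- in_anchor | sel
    span <- span + (a[2] - a[1])
  }
  xa <- spec$axis[in_anchor]
  ya <- spec$intensity[in_anchor]
  df <- min(max(4, round(span / knot_spacing)), length(xa) - 1)
  sfit <- stats::smooth.spline(xa, ya, df = df)
  baseline <- stats::predict(sfit, spec$axis)$y
  corrected <- spec$intensity - baseline
  resid_anchor <- corrected[in_anchor]
  peak <- max(abs(spec$intensity))
  if (abs(mean(resid_anchor)) > 0.01 * peak) {
    warning("anchor-region residual mean exceeds 1% of peak intensity: ",
            "baseline fit may be poor")
  }
  list(corrected = spectrum(spec$axis, corrected, kind = spec$kind,
                            meta = spec$meta,
                            min_points = min(16L, length(spec$axis))),
       baseline = spectrum(spec$axis, baseline, kind = spec$kind,
                           min_points = min(16L, length(spec$axis))),
       baseline_rss = sum(resid_anchor^2))
}

#' Subtract a scaled reference spectrum
#'
#' @param sample,reference spectra on the same axis.
#' @param alpha non-negative scale factor.
#' @return residual [spectrum]; `meta$negative_integral` is set when the
#'   integrated residual is negative (over-subtraction diagnostic).
#' @export
subtract_scaled <- function(sample, reference, alpha) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  if (length(sample$axis) != length(reference$axis) ||
      max(abs(sample$axis - reference$axis)) > 1e-9) {
    stop("sample and reference are not on the same axis; resample first",
         call. = FALSE)
  }
  out_int <- sample$intensity - alpha * reference$intensity
  meta <- sample$meta
  if (.trapz(sample$axis, out_int) < 0) meta$negative_integral <- TRUE
  spectrum(sample$axis, out_int, kind = sample$kind, meta = meta,
           min_points = min(16L, length(sample$axis)))
}

#' Integrate a band area
#'
#' Trapezoidal integral of the intensity over a window, with negative
#' excursions clipped at `clip_floor` (default 0) inside the integration
#' only; stored residual spectra are never clipped.
#'
#' @param spec a [spectrum].
#' @param window `c(lo, hi)` in axis units.
#' @param clip_floor lower clip applied during integration.
#' @return the band area (axis unit x intensity unit).
#' @export
integrate_band <- function(spec, window, clip_floor = 0) {
  stopifnot(inherits(spec, "spectrum"), length(window) == 2)
  if (window[1] < min(spec$axis) || window[2] > max(spec$axis)) {
    stop("integration window [", window[1], ", ", window[2],
         "] outside the spectral axis", call. = FALSE)
  }
  sel <- spec$axis >= window[1] & spec$axis <= window[2]
  .trapz(spec$axis[sel], pmax(spec$intensity[sel], clip_floor))
}

# Least-squares projection coefficient of y onto shape over a logical index.
.proj_coef <- function(y, shape, idx) {
  denom <- sum(shape[idx]^2)
  if (denom <= 0) return(0)
  sum(y[idx] * shape[idx]) / denom
}

#' Optimize the PDMS and medium subtraction factors
#'
#' Determines the two normalization factors so that, after subtracting
#' `alpha_pdms * pdms` and `alpha_medium * medium` from the sample, the
#' residual CH band matches the CH band of the off-chip spheroid reference.
#' The medium subtraction is responsible for removing the entire OH
#' contribution (spheroid water plus chip medium), isolating the CH band.
#'
#' Concretely the search minimizes, over `alpha` in `bounds`, the sum of
#' (i) the squared residual over the OH window (pins `alpha_medium`) and
#' (ii) the squared CH-window mismatch against the reference CH band shape
#' with a free non-negative amplitude (pins `alpha_pdms` while leaving the
#' sample's own dry-mass amplitude unconstrained, so composition differences
#' between sample and reference are not absorbed into the factors). The
#' optimization is a bounded quasi-Newton search with seeded multistarts.
#'
#' @param sample baseline-corrected raman [spectrum].
#' @param refs [raman_references], baseline-corrected, resampled to the
#'   sample axis (done internally if axes differ).
#' @param windows [band_windows].
#' @param bounds search box for each factor (default c(0, 2)).
#' @param n_starts number of multistarts (default 5).
#' @param seed seed for the multistart draws.
#' @return list with `alpha_pdms`, `alpha_medium`, `objective`,
#'   `ch_scale` (fitted CH amplitude relative to the reference) and
#'   `ch_area_mismatch` (residual CH-area difference vs the scaled
#'   reference band).
#' @export
optimize_factors <- function(sample, refs, windows = band_windows(),
                             bounds = c(0, 2), n_starts = 5, seed = 1L) {
  stopifnot(inherits(sample, "spectrum"), inherits(refs, "raman_references"))
  x <- sample$axis
  P <- resample_to(refs$pdms, x)$intensity
  M <- resample_to(refs$medium, x)$intensity
  O <- resample_to(refs$offchip, x)$intensity
  y <- sample$intensity
  idx_oh <- x >= windows$oh[1] & x <= windows$oh[2]
  idx_ch <- x >= windows$ch[1] & x <= windows$ch[2]

  # Reference CH band: strip the off-chip spheroid's own OH content via the
  # same medium projection used for samples.
  am_off <- .proj_coef(O, M, idx_oh)
  ch_ref <- O - am_off * M

  objective <- function(a) {
    r <- y - a[1] * P - a[2] * M
    s_hat <- max(.proj_coef(r, ch_ref, idx_ch), 0)
    sum(r[idx_oh]^2) + sum((r[idx_ch] - s_hat * ch_ref[idx_ch])^2)
  }

  # On the branch where the CH amplitude is unclamped, the objective is an
  # exact linear least-squares problem: stack the OH-window rows with the
  # CH-window rows projected orthogonal to the reference CH shape. Solve it
  # directly; accept the solution when it is interior and self-consistent
  # (global minimum of a convex quadratic), otherwise fall back to the
  # bounded multistart search.
  chn <- ch_ref[idx_ch]
  qproj <- function(v) v - chn * (sum(v * chn) / sum(chn^2))
  A <- cbind(c(P[idx_oh], qproj(P[idx_ch])),
             c(M[idx_oh], qproj(M[idx_ch])))
  b <- c(y[idx_oh], qproj(y[idx_ch]))
  best <- NULL
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (!is.null(sol) && all(is.finite(sol)) &&
      all(sol >= bounds[1]) && all(sol <= bounds[2]) &&
      .proj_coef(y - sol[1] * P - sol[2] * M, ch_ref, idx_ch) >= 0) {
    best <- list(par = as.numeric(sol), value = objective(sol))
  }
  if (is.null(best)) {
    starts <- .with_seed(seed, {
      rbind(c(mean(bounds), mean(bounds)),
            matrix(stats::runif(2 * (n_starts - 1), bounds[1], bounds[2]),
                   ncol = 2))
    })
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                     lower = bounds[1], upper = bounds[2]),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("subtraction-factor optimization failed from all starts",
         call. = FALSE)
  }
  r <- y - best$par[1] * P - best$par[2] * M
  s_hat <- max(.proj_coef(r, ch_ref, idx_ch), 0)
  res_spec <- spectrum(x, r - s_hat * ch_ref, kind = "raman",
                       min_points = min(16L, length(x)))
  area_mismatch <- abs(integrate_band(
    spectrum(x, r, kind = "raman", min_points = min(16L, length(x))),
    windows$ch, clip_floor = -Inf) -
      s_hat * integrate_band(
        spectrum(x, ch_ref, kind = "raman",
                 min_points = min(16L, length(x))),
        windows$ch, clip_floor = -Inf))
  list(alpha_pdms = unname(best$par[1]), alpha_medium = unname(best$par[2]),
       objective = best$value, ch_scale = s_hat,
       ch_area_mismatch = area_mismatch)
}

#' Full CH/OH ratio pipeline for one Raman spectrum
#'
#' Fixed processing order: fluorescence baseline removal, subtraction-factor
#' optimization, PDMS subtraction, OH-band integration, medium subtraction
#' (which removes the OH contribution and isolates the CH band), CH-band
#' integration. `a_oh` is measured on the PDMS-subtracted spectrum before
#' the medium subtraction removes the water signal; `a_ch` on the fully
#' subtracted spectrum.
#'
#' @param sample raw raman [spectrum] (fluorescence baseline still present).
#' @param refs [raman_references]; assumed baseline-free (averaged reference
#'   acquisitions); set `baseline_refs = TRUE` to baseline-correct them with
#'   the same spline settings.
#' @param windows [band_windows].
#' @param knot_spacing,anchor_regions passed to [remove_baseline()].
#' @param baseline_refs also baseline-correct the references.
#' @param ... passed to [optimize_factors()].
#' @return list of class `raman_result`: `a_ch`, `a_oh`, `ratio`,
#'   `alpha_pdms`, `alpha_medium`, `baseline_rss`, `objective`, plus the
#'   isolated CH spectrum for diagnostics.
#' @export
ch_oh_ratio <- function(sample, refs, windows = band_windows(),
                        knot_spacing = 50,
                        anchor_regions = list(c(2600, 2750), c(3750, 3900)),
                        baseline_refs = FALSE, ...) {
  bl <- remove_baseline(sample, knot_spacing = knot_spacing,
                        anchor_regions = anchor_regions, windows = windows)
  s <- bl$corrected
  if (baseline_refs) {
    refs <- raman_references(
      pdms = remove_baseline(refs$pdms, knot_spacing, anchor_regions)$corrected,
      medium = remove_baseline(refs$medium, knot_spacing,
                               anchor_regions)$corrected,
      offchip = remove_baseline(refs$offchip, knot_spacing,
                                anchor_regions)$corrected)
  }
  refs_rs <- raman_references(pdms = resample_to(refs$pdms, s$axis),
                              medium = resample_to(refs$medium, s$axis),
                              offchip = resample_to(refs$offchip, s$axis))
  fac <- optimize_factors(s, refs_rs, windows, ...)
  after_pdms <- subtract_scaled(s, refs_rs$pdms, fac$alpha_pdms)
  a_oh <- integrate_band(after_pdms, windows$oh)
  isolated_ch <- subtract_scaled(after_pdms, refs_rs$medium,
                                 fac$alpha_medium)
  a_ch <- integrate_band(isolated_ch, windows$ch)
  if (a_oh <= 0) {
    stop("non-positive OH band area: OH isolation failed", call. = FALSE)
  }
  structure(list(a_ch = a_ch, a_oh = a_oh, ratio = a_ch / a_oh,
                 alpha_pdms = fac$alpha_pdms,
                 alpha_medium = fac$alpha_medium,
                 baseline_rss = bl$baseline_rss,
                 objective = fac$objective,
                 isolated_ch = isolated_ch),
            class = "raman_result")
}

#' @export
print.raman_result <- function(x, ...) {
  cat(sprintf("<Raman result> A_CH = %.4g, A_OH = %.4g, R = %.4f\n",
              x$a_ch, x$a_oh, x$ratio))
  cat(sprintf("  alpha_pdms = %.3f, alpha_medium = %.3f\n",
              x$alpha_pdms, x$alpha_medium))
  invisible(x)
}
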