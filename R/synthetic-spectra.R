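# Synthetic-data generator: seeded Brillouin and Raman spectra with known
# ground truth, emulating the statistical structure the analysis assumes --
# two merged DHO components obeying the linear mixture, and CH/OH bands
# whose areas encode the biphasic composition.

# Overall Raman area scale (arbitrary instrument units); band shapes below
# are unit-area mixtures multiplied by analytic compartment areas.
.raman_scale <- 1000

.ch_centers <- c(2850, 2885, 2935)
.ch_sigmas  <- c(28, 22, 30)
.ch_weights <- c(0.35, 0.25, 0.40)
.oh_centers <- c(3230, 3420)
.oh_sigmas  <- c(100, 95)
.oh_weights <- c(0.55, 0.45)
.pdms_centers <- c(2905, 2965)
.pdms_sigmas  <- c(14, 12)
.pdms_weights <- c(0.5, 0.5)

# Unit-total-area Gaussian mixture.
.gauss_mix <- function(axis, centers, sigmas, weights) {
  weights <- weights / sum(weights)
  out <- numeric(length(axis))
  for (k in seq_along(centers)) {
    out <- out + weights[k] *
      stats::dnorm(axis, mean = centers[k], sd = sigmas[k])
  }
  out
}

#' Ground-truth generative parameters for one experimental condition
#'
#' Presets pin the composition and component shifts that each condition
#' emulates: the control ECM fraction (0.15) and its ROCK-inhibited
#' increase (0.24), the ECM component shift (8.0 GHz), the vanishing
#' interstitial fraction under compression, and the 70/30 cell water/dry
#' split. Component cell shifts, linewidths, the CH/OH efficiency constant
#' and noise levels are generator choices preserving the ordinal
#' relationships between conditions; every value is recorded in the emitted
#' ground truth and overridable via `...`.
#'
#' @param name condition label.
#' @param ... named overrides of any preset field (`phi_ecm`, `omega_cell`,
#'   `omega_ecm`, `gamma`, `w_cell`, `kappa`, `noise_snr`,
#'   `baseline_coeffs`, `pdms_level`, `medium_level`).
#' @return list of class `condition_preset`.
#' @export
condition_preset <- function(name = c("control", "rock", "rhoa",
                                      "compressed", "flow", "cycle1",
                                      "cycle4"), ...) {
  name <- match.arg(name)
  base <- list(name = name, phi_ecm = 0.15, omega_cell = 8.20,
               omega_ecm = 8.00, gamma = 1.2, w_cell = 0.70, kappa = 0.7,
               noise_snr = 50,
               baseline_coeffs = c(1.0, -0.6, 0.15, -0.05),
               pdms_level = 0.2, medium_level = 0.2)
  tweak <- switch(name,
    control    = list(),
    rock       = list(phi_ecm = 0.24, omega_cell = 8.10),
    rhoa       = list(omega_cell = 8.28, gamma = 1.5),
    compressed = list(phi_ecm = 0),
    flow       = list(omega_cell = 8.22),
    cycle1     = list(omega_cell = 8.24),
    cycle4     = list(omega_cell = 8.30))
  preset <- utils::modifyList(base, tweak)
  preset <- utils::modifyList(preset, list(...))
  stopifnot(preset$phi_ecm >= 0, preset$phi_ecm <= 0.5,
            preset$omega_cell >= 6, preset$omega_cell <= 10,
            preset$omega_ecm >= 6, preset$omega_ecm <= 10,
            preset$gamma >= 0.3, preset$gamma <= 3,
            preset$noise_snr > 0)
  structure(preset, class = "condition_preset")
}

#' Generate a synthetic Brillouin spectrum
#'
#' The signal is a sum of two DHO pairs -- the cell component at
#' `+/-omega_cell` weighted by `1 - phi_ecm` and the ECM component at
#' `+/-omega_ecm` weighted by `phi_ecm` -- plus the Lorentzian tail of the
#' elastic line, a small flat dark background, and Poisson counting noise
#' scaled so the Brillouin peak signal-to-noise equals the preset's
#' `noise_snr`. The two components are generated separately (never
#' pre-mixed) so that the single-DHO linearization is a testable property.
#'
#' @param preset a [condition_preset].
#' @param seed integer seed (deterministic output).
#' @param n_points number of spectral points.
#' @param span `c(lo, hi)` frequency range in GHz; must cover
#'   `+/-(omega + 3 gamma)`.
#' @param elastic_amp elastic-line tail amplitude relative to the Brillouin
#'   peak (default 10; set 0 for a tail-free spectrum).
#' @param elastic_width Lorentzian half-width of the elastic line, GHz.
#' @param noiseless skip the Poisson noise (continuous intensities).
#' @return list with `spectrum` and `truth` (all generative parameters,
#'   including the linear-mixture composite shift `omega_b_linear`).
#' @export
make_brillouin <- function(preset, seed = 1L, n_points = 800,
                           span = c(-15, 15), elastic_amp = 10,
                           elastic_width = 0.1, noiseless = FALSE) {
  stopifnot(inherits(preset, "condition_preset"))
  need <- max(preset$omega_cell, preset$omega_ecm) + 3 * preset$gamma
  if (span[1] > -need || span[2] < need) {
    stop(sprintf("span must cover +/-%.2f GHz", need), call. = FALSE)
  }
  nu <- seq(span[1], span[2], length.out = n_points)
  phi_c <- 1 - preset$phi_ecm
  shape <- phi_c * .dho(nu, preset$omega_cell, preset$gamma, 1) +
    preset$phi_ecm * .dho(nu, preset$omega_ecm, preset$gamma, 1)
  peak <- max(shape)
  shape <- shape +
    elastic_amp * peak * elastic_width^2 / (nu^2 + elastic_width^2) +
    0.02 * peak
  # Poisson SNR at the peak is sqrt(counts); scale so it equals noise_snr.
  scale <- preset$noise_snr^2 / peak
  lambda <- shape * scale
  intensity <- if (noiseless) {
    lambda
  } else {
    .with_seed(seed, stats::rpois(length(lambda), lambda))
  }
  sp <- spectrum(nu, intensity, kind = "brillouin",
                 meta = list(condition = preset$name))
  truth <- c(unclass(preset),
             list(seed = seed, n_points = n_points, span = span,
                  elastic_amp = elastic_amp, elastic_width = elastic_width,
                  noiseless = noiseless, count_scale = scale,
                  omega_b_linear = forward_omega(preset$omega_cell,
                                                 preset$omega_ecm,
                                                 preset$phi_ecm)))
  list(spectrum = sp, truth = truth)
}

# Analytic compartment band areas for a preset (raman area units).
.raman_truth_areas <- function(preset, w_ecm = 1.0) {
  phi_c <- 1 - preset$phi_ecm
  d_cell <- 1 - preset$w_cell
  a_ch <- .raman_scale * preset$kappa * d_cell * phi_c
  a_oh <- .raman_scale * (preset$w_cell * phi_c + w_ecm * preset$phi_ecm)
  list(a_ch = a_ch, a_oh = a_oh, ratio = a_ch / a_oh)
}

# Reference amplitudes: the PDMS reference carries the CH-band area of a
# control spheroid, the medium reference its OH-band area, so contamination
# levels are dimensionless fractions of typical band intensity.
.ref_areas <- function() {
  ctrl <- .raman_truth_areas(condition_preset("control"))
  list(pdms = ctrl$a_ch, medium = ctrl$a_oh)
}

#' Generate a synthetic high-wavenumber Raman spectrum
#'
#' The CH band is a three-Gaussian mixture (2850/2885/2935 cm^-1) with
#' total area proportional to `kappa * d_cell * phi_cell`; the OH band a
#' two-Gaussian mixture (3230/3420 cm^-1) with area proportional to the
#' total water volume `w_cell * phi_cell + phi_ecm`. On-chip acquisitions
#' add a PDMS doublet (2905/2965 cm^-1) and excess culture-medium OH at the
#' preset contamination levels, plus a polynomial fluorescence baseline and
#' Gaussian detector noise.
#'
#' @param preset a [condition_preset].
#' @param seed integer seed.
#' @param with_pdms,with_medium include the respective contamination.
#' @param axis Raman-shift axis in cm^-1 (default 2400-4000, 2 cm^-1 step).
#' @param noiseless skip the Gaussian noise.
#' @return list with `spectrum` and `truth`; the truth records the analytic
#'   band areas, the contamination levels and the optimal subtraction
#'   factors `alpha_pdms_true` (= pdms_level) and `alpha_medium_true`
#'   (= medium_level + sample OH amplitude relative to the medium
#'   reference, since the medium subtraction removes the entire OH
#'   contribution).
#' @export
make_raman <- function(preset, seed = 1L, with_pdms = TRUE,
                       with_medium = TRUE, axis = seq(2400, 4000, by = 2),
                       noiseless = FALSE) {
  stopifnot(inherits(preset, "condition_preset"))
  areas <- .raman_truth_areas(preset)
  refa <- .ref_areas()
  ch_shape <- .gauss_mix(axis, .ch_centers, .ch_sigmas, .ch_weights)
  oh_shape <- .gauss_mix(axis, .oh_centers, .oh_sigmas, .oh_weights)
  pdms_shape <- .gauss_mix(axis, .pdms_centers, .pdms_sigmas, .pdms_weights)
  p_level <- if (with_pdms) preset$pdms_level else 0
  m_level <- if (with_medium) preset$medium_level else 0
  signal <- areas$a_ch * ch_shape + areas$a_oh * oh_shape +
    p_level * refa$pdms * pdms_shape + m_level * refa$medium * oh_shape
  xx <- (axis - 3200) / 800
  peak <- max(signal)
  baseline <- peak * drop(cbind(1, xx, xx^2, xx^3) %*% preset$baseline_coeffs)
  intensity <- signal + baseline
  if (!noiseless) {
    noise_sd <- peak / preset$noise_snr
    intensity <- intensity +
      .with_seed(seed, stats::rnorm(length(axis), 0, noise_sd))
  }
  sp <- spectrum(axis, intensity, kind = "raman",
                 meta = list(condition = preset$name))
  truth <- c(unclass(preset),
             list(seed = seed, noiseless = noiseless,
                  a_ch_analytic = areas$a_ch, a_oh_analytic = areas$a_oh,
                  ratio_analytic = areas$ratio,
                  with_pdms = with_pdms, with_medium = with_medium,
                  alpha_pdms_true = p_level,
                  alpha_medium_true = m_level + areas$a_oh / refa$medium))
  list(spectrum = sp, truth = truth)
}

#' Generate the three Raman reference spectra
#'
#' The PDMS reference contains only the chip doublet, the medium reference
#' only the OH band, and the off-chip reference is a contamination-free
#' control-preset spheroid spectrum. References model long averaged
#' acquisitions: noiseless and baseline-free by default.
#'
#' @param seed integer seed (used only when `noise_snr` is finite).
#' @param axis Raman-shift axis.
#' @param noise_snr peak signal-to-noise of the references (Inf =
#'   noiseless).
#' @return a [raman_references] object; the off-chip truth areas are
#'   attached as attribute `truth`.
#' @export
make_reference_set <- function(seed = 1L, axis = seq(2400, 4000, by = 2),
                               noise_snr = Inf) {
  refa <- .ref_areas()
  ctrl <- condition_preset("control")
  areas <- .raman_truth_areas(ctrl)
  pdms_int <- refa$pdms * .gauss_mix(axis, .pdms_centers, .pdms_sigmas,
                                     .pdms_weights)
  medium_int <- refa$medium * .gauss_mix(axis, .oh_centers, .oh_sigmas,
                                         .oh_weights)
  offchip_int <- areas$a_ch *
    .gauss_mix(axis, .ch_centers, .ch_sigmas, .ch_weights) +
    areas$a_oh * .gauss_mix(axis, .oh_centers, .oh_sigmas, .oh_weights)
  if (is.finite(noise_snr)) {
    .with_seed(seed, {
      pdms_int <- pdms_int + stats::rnorm(length(axis), 0,
                                          max(pdms_int) / noise_snr)
      medium_int <- medium_int + stats::rnorm(length(axis), 0,
                                              max(medium_int) / noise_snr)
      offchip_int <- offchip_int + stats::rnorm(length(axis), 0,
                                                max(offchip_int) / noise_snr)
    })
  }
  refs <- raman_references(
    pdms = spectrum(axis, pdms_int, kind = "raman",
                    meta = list(role = "pdms")),
    medium = spectrum(axis, medium_int, kind = "raman",
                      meta = list(role = "medium")),
    offchip = spectrum(axis, offchip_int, kind = "raman",
                       meta = list(role = "offchip")))
  attr(refs, "truth") <- list(offchip_a_ch = areas$a_ch,
                              offchip_a_oh = areas$a_oh)
  refs
}
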