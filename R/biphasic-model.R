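# Biphasic cell/ECM composition model.
#
# A spheroid is modelled as two compartments: cells with a fixed water/dry
# mass split (w_cell ~ 0.70 / d_cell ~ 0.30 by volume) and a predominantly
# aqueous extracellular matrix (w_ecm ~ 1, negligible dry mass). The Raman
# OH band area is proportional to the total water volume in the probed
# region, the CH band area to the total dry-mass volume, with one
# scattering-efficiency constant kappa relating the two bands:
#
#   R = A_CH / A_OH = kappa * d_cell * Phi_cell /
#                     (w_cell * Phi_cell + w_ecm * Phi_ECM)
#
# The measured Brillouin shift mixes the two compartments linearly because
# their peaks are too close to resolve:
#
#   omega_B = omega_ECM * Phi_ECM + omega_cell * Phi_cell.

#' Define a biphasic composition model
#'
#' @param w_cell water volume fraction of cells (default 0.70; dry-mass
#'   fraction is its exact complement).
#' @param w_ecm water volume fraction of the ECM (default 1: predominantly
#'   aqueous, negligible dry mass).
#' @param kappa CH-vs-OH scattering-efficiency calibration constant
#'   (> 0); set by [calibrate_kappa()], NA until calibrated.
#' @return list of class `composition_model`.
#' @export
composition_model <- function(w_cell = 0.70, w_ecm = 1.0, kappa = NA_real_) {
  stopifnot(w_cell > 0, w_cell < 1, w_ecm > 0, w_ecm <= 1)
  if (!is.na(kappa) && kappa <= 0) stop("kappa must be positive",
                                        call. = FALSE)
  structure(list(w_cell = w_cell, d_cell = 1 - w_cell, w_ecm = w_ecm,
                 kappa = kappa),
            class = "composition_model")
}

# Model ratio R(Phi_ECM) under a composition model.
.model_ratio <- function(phi_ecm, model) {
  phic <- 1 - phi_ecm
  model$kappa * model$d_cell * phic /
    (model$w_cell * phic + model$w_ecm * phi_ecm)
}

#' Calibrate the scattering-efficiency constant kappa
#'
#' Solves the model ratio relation for kappa using a reference sample of
#' known composition, typically a compressed spheroid whose interstitial
#' spaces are negligible (Phi_ECM ~ 0).
#'
#' @param r_ref measured CH/OH ratio of the reference.
#' @param phi_ecm_ref known ECM volume fraction of the reference.
#' @param model a [composition_model] (kappa ignored).
#' @return the model with `kappa` set.
#' @export
calibrate_kappa <- function(r_ref, phi_ecm_ref, model = composition_model()) {
  stopifnot(r_ref >= 0, phi_ecm_ref >= 0, phi_ecm_ref <= 1)
  if (phi_ecm_ref >= 1) {
    stop("phi_ecm_ref = 1 has no CH signal: kappa is undefined",
         call. = FALSE)
  }
  phic <- 1 - phi_ecm_ref
  kappa <- r_ref * (model$w_cell * phic + model$w_ecm * phi_ecm_ref) /
    (model$d_cell * phic)
  if (kappa <= 0) stop("calibration produced non-positive kappa",
                       call. = FALSE)
  model$kappa <- kappa
  model
}

#' Estimate cell and ECM volume fractions from a CH/OH ratio
#'
#' Inverts the biphasic ratio relation:
#' \deqn{\Phi_{ECM} = (\kappa d_{cell} - R w_{cell}) /
#'   (\kappa d_{cell} - R w_{cell} + R w_{ecm})}
#' Noise-driven slightly negative estimates (down to -0.05) are clamped to
#' zero with a warning; larger violations indicate a composition
#' incompatible with the biphasic assumptions and are errors.
#'
#' @param r measured CH/OH band-area ratio (>= 0).
#' @param model calibrated [composition_model].
#' @param se_r optional standard error of `r` for first-order uncertainty
#'   propagation.
#' @return list of class `composition_estimate` with `phi_ecm`, `phi_cell`
#'   (exact complement) and `se_phi`.
#' @export
estimate_phi <- function(r, model, se_r = NULL) {
  stopifnot(inherits(model, "composition_model"))
  if (is.na(model$kappa)) stop("model kappa is not calibrated",
                               call. = FALSE)
  if (r < 0) stop("ratio must be non-negative", call. = FALSE)
  num <- model$kappa * model$d_cell - r * model$w_cell
  den <- num + r * model$w_ecm
  phi <- num / den
  if (phi < -0.05 || phi > 1.05) {
    stop(sprintf(
      "estimated Phi_ECM = %.3f outside [-0.05, 1.05]: composition ",
      phi), "incompatible with the biphasic model", call. = FALSE)
  }
  clamped <- FALSE
  if (phi < 0) {
    warning(sprintf("Phi_ECM = %.3f clamped to 0 (noise floor)", phi))
    phi <- 0
    clamped <- TRUE
  }
  if (phi > 1) phi <- 1
  se_phi <- NA_real_
  if (!is.null(se_r) && !clamped) {
    # dPhi/dr by the quotient rule on num/den.
    dnum <- -model$w_cell
    dden <- -model$w_cell + model$w_ecm
    dphi <- (dnum * den - num * dden) / den^2
    se_phi <- abs(dphi) * se_r
  }
  structure(list(phi_ecm = phi, phi_cell = 1 - phi, se_phi = se_phi,
                 clamped = clamped, ratio = r),
            class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat(sprintf("<composition> Phi_ECM = %.1f%%, Phi_cell = %.1f%%%s\n",
              100 * x$phi_ecm, 100 * x$phi_cell,
              if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Is the ECM fraction operationally negligible?
#'
#' Under strong compression the interstitial spaces become negligible for
#' Brillouin measurements; an estimated fraction below `threshold`
#' (default 0.02) is treated as exactly zero.
#'
#' @param est a `composition_estimate` or a bare fraction.
#' @param threshold negligibility threshold.
#' @return logical.
#' @export
is_negligible_ecm <- function(est, threshold = 0.02) {
  phi <- if (inherits(est, "composition_estimate")) est$phi_ecm else est
  phi < threshold
}

#' Composite Brillouin shift of the biphasic mixture
#'
#' @param omega_cell,omega_ecm component shifts, GHz.
#' @param phi_ecm ECM volume fraction in [0, 1].
#' @return composite shift `omega_b` in GHz.
#' @export
forward_omega <- function(omega_cell, omega_ecm, phi_ecm) {
  if (any(phi_ecm < 0 | phi_ecm > 1)) {
    stop("phi_ecm must lie in [0, 1]", call. = FALSE)
  }
  omega_ecm * phi_ecm + omega_cell * (1 - phi_ecm)
}

#' Invert the mixture for the ECM component shift
#'
#' Given the composite shift, the cell shift (e.g. measured on a compressed
#' spheroid, where the composite coincides with the cell component) and the
#' ECM fraction, recovers the ECM component shift.
#'
#' @param omega_b composite shift, GHz.
#' @param omega_cell cell component shift, GHz.
#' @param phi_ecm ECM fraction; must be at least `phi_min`.
#' @param phi_min ill-conditioning guard (default 0.02).
#' @param se optional named list with `omega_b`, `omega_cell`, `phi_ecm`
#'   standard errors for first-order propagation.
#' @return `omega_ecm` in GHz (with attribute `se` when `se` given).
#' @export
invert_omega_ecm <- function(omega_b, omega_cell, phi_ecm, phi_min = 0.02,
                             se = NULL) {
  if (any(phi_ecm < phi_min)) {
    stop(sprintf(
      "phi_ecm = %.3g below phi_min = %.3g: inversion ill-conditioned",
      min(phi_ecm), phi_min), call. = FALSE)
  }
  out <- (omega_b - (1 - phi_ecm) * omega_cell) / phi_ecm
  if (!is.null(se)) {
    d_b <- 1 / phi_ecm
    d_c <- -(1 - phi_ecm) / phi_ecm
    d_p <- (omega_cell * phi_ecm - (omega_b - (1 - phi_ecm) * omega_cell)) /
      phi_ecm^2
    attr(out, "se") <- sqrt((d_b * (se$omega_b %||% 0))^2 +
                              (d_c * (se$omega_cell %||% 0))^2 +
                              (d_p * (se$phi_ecm %||% 0))^2)
  }
  out
}

#' Invert the mixture for the cell component shift
#'
#' @inheritParams invert_omega_ecm
#' @param omega_ecm ECM component shift, GHz.
#' @return `omega_cell` in GHz.
#' @export
invert_omega_cell <- function(omega_b, omega_ecm, phi_ecm, phi_min = 0.02) {
  if (any(phi_ecm > 1 - phi_min)) {
    stop(sprintf(
      "phi_ecm = %.3g above 1 - phi_min: inversion ill-conditioned",
      max(phi_ecm)), call. = FALSE)
  }
  (omega_b - phi_ecm * omega_ecm) / (1 - phi_ecm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
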