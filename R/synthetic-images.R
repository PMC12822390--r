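# Synthetic morphometry images with known ground truth: nuclei label
# images with zone-dependent aspect ratios, invasion core/total masks with
# analytic areas, marker-intensity mixtures, and interstitial-dye images.

# Rasterize an ellipse (center cx, cy; semi-axes a >= b; orientation theta)
# onto a logical matrix of the given dimensions.
.raster_ellipse <- function(dim, cx, cy, a, b, theta) {
  xr <- max(1, floor(cx - a)):min(dim[1], ceiling(cx + a))
  yr <- max(1, floor(cy - a)):min(dim[2], ceiling(cy + a))
  gx <- outer(xr, rep(1, length(yr))) - cx
  gy <- outer(rep(1, length(xr)), yr) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(x = xr, y = yr, inside = inside)
}

#' Generate a synthetic nuclei label image inside a spheroid mask
#'
#' Nuclei are non-overlapping ellipses of fixed area with aspect ratios
#' drawn per zone: peripheral nuclei (centroid within `band` pixels of the
#' mask boundary) have mean aspect ratio `ar_mean + zone_effect`, central
#' ones `ar_mean`. Orientations are uniform. Placement uses rejection
#' sampling with bounded retries.
#'
#' @param n number of nuclei.
#' @param ar_mean mean aspect ratio of central nuclei.
#' @param ar_sd aspect-ratio standard deviation.
#' @param zone_effect additive peripheral aspect-ratio shift.
#' @param seed integer seed.
#' @param size image side length in pixels.
#' @param nucleus_area target nucleus area, pixels^2.
#' @param band periphery band width in pixels (also recorded for use with
#'   [classify_zone()]).
#' @param max_retries placement attempts per nucleus before a packing
#'   error.
#' @return list with `labels` (integer matrix), `mask` (0/1 spheroid disk),
#'   `truth` (data.frame: label, centroid, semi-axes, theta, `ar_true`,
#'   `zone_true`) and `band`.
#' @export
make_nuclei_image <- function(n = 200, ar_mean = 1.3, ar_sd = 0.15,
                              zone_effect = 0, seed = 1L, size = 512,
                              nucleus_area = 250, band = 25,
                              max_retries = 400) {
  R <- 0.45 * size
  cx0 <- cy0 <- (size + 1) / 2
  labels <- matrix(0L, size, size)
  gx <- outer(seq_len(size), rep(1, size)) - cx0
  gy <- outer(rep(1, size), seq_len(size)) - cy0
  mask <- matrix(as.integer(sqrt(gx^2 + gy^2) <= R), size, size)
  truth <- vector("list", n)
  .with_seed(seed, {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        r <- R * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        cx <- cx0 + r * cos(th)
        cy <- cy0 + r * sin(th)
        dist_boundary <- R - r
        zone <- if (dist_boundary <= band) "periphery" else "center"
        ar <- max(1.02, stats::rnorm(
          1, ar_mean + if (zone == "periphery") zone_effect else 0, ar_sd))
        b <- sqrt(nucleus_area / (pi * ar))
        a <- ar * b
        if (dist_boundary < a + 1) next  # nucleus must fit inside the mask
        ori <- stats::runif(1, 0, pi)
        re <- .raster_ellipse(dim(labels), cx, cy, a, b, ori)
        patch <- labels[re$x, re$y]
        if (any(patch[re$inside] != 0)) next
        patch[re$inside] <- i
        labels[re$x, re$y] <- patch
        truth[[i]] <- data.frame(label = i, cx = cx, cy = cy, a = a, b = b,
                                 theta = ori, ar_true = ar,
                                 dist_boundary = dist_boundary,
                                 zone_true = zone)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "failed to place nucleus %d of %d after %d retries (packing)",
          i, n, max_retries), call. = FALSE)
      }
    }
  })
  list(labels = labels, mask = mask, truth = do.call(rbind, truth),
       band = band)
}

#' Generate matched invasion core/total masks with analytic areas
#'
#' The core is a disk; the invasive halo is a set of disjoint annular
#' sectors between `core_radius` and `core_radius + spread`, one per
#' protrusion, with random angular widths. All areas are analytic.
#'
#' @param core_radius core disk radius, pixels.
#' @param spread radial extent of the protrusions, pixels (0 = none).
#' @param n_protrusions number of protrusions.
#' @param seed integer seed.
#' @param size image side (default fits the geometry).
#' @return list with `core`, `total` (0/1 matrices) and `truth`
#'   (`core_area`, `invasive_area`, `ratio`, all analytic).
#' @export
make_invasion_masks <- function(core_radius = 60, spread = 40,
                                n_protrusions = 6, seed = 1L, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(core_radius + spread + 8)
  c0 <- (size + 1) / 2
  gx <- outer(seq_len(size), rep(1, size)) - c0
  gy <- outer(rep(1, size), seq_len(size)) - c0
  rr <- sqrt(gx^2 + gy^2)
  core <- matrix(as.integer(rr <= core_radius), size, size)
  total <- core
  invasive_area <- 0
  if (spread > 0 && n_protrusions > 0) {
    slot <- 2 * pi / n_protrusions
    sect <- .with_seed(seed, {
      widths <- stats::runif(n_protrusions, 0.15, min(0.35, slot * 0.9))
      starts <- (seq_len(n_protrusions) - 1) * slot +
        stats::runif(n_protrusions, 0, slot - widths)
      cbind(starts, widths)
    })
    ang <- (atan2(gy, gx) + 2 * pi) %% (2 * pi)
    halo <- rr > core_radius & rr <= core_radius + spread
    for (k in seq_len(n_protrusions)) {
      in_sector <- ang >= sect[k, 1] & ang < sect[k, 1] + sect[k, 2]
      total[halo & in_sector] <- 1L
    }
    invasive_area <- sum(sect[, 2]) / 2 *
      ((core_radius + spread)^2 - core_radius^2)
  }
  core_area <- pi * core_radius^2
  list(core = core, total = total,
       truth = list(core_area = core_area, invasive_area = invasive_area,
                    ratio = invasive_area / core_area))
}

#' Generate a two-population marker-intensity mixture
#'
#' Emulates immunostaining intensities in which a fraction of nuclei is
#' marker-positive, shifted upward from the control (secondary-only)
#' distribution by a multiple of its SD.
#'
#' @param n number of nuclei.
#' @param frac_positive fraction of positive nuclei.
#' @param shift_sd positive-population shift in control SD units.
#' @param control_mean,control_sd control distribution parameters.
#' @param n_control size of the control sample.
#' @param seed integer seed.
#' @return list with `intensities`, `is_positive_true`,
#'   `control_intensities`.
#' @export
make_marker_intensities <- function(n = 200, frac_positive = 0.3,
                                    shift_sd = 5, control_mean = 100,
                                    control_sd = 10, n_control = 100,
                                    seed = 1L) {
  .with_seed(seed, {
    pos <- stats::runif(n) < frac_positive
    vals <- stats::rnorm(n, control_mean + ifelse(pos, shift_sd * control_sd,
                                                  0), control_sd)
    ctrl <- stats::rnorm(n_control, control_mean, control_sd)
    list(intensities = vals, is_positive_true = pos,
         control_intensities = ctrl)
  })
}

#' Generate a synthetic interstitial-dye (dextran) image
#'
#' The spheroid interior carries the interstitial dye level on top of a
#' uniform background; pixels outside the mask carry background only.
#'
#' @param level interstitial intensity above background.
#' @param background uniform background level.
#' @param noise_sd additive Gaussian noise SD.
#' @param size image side, pixels.
#' @param seed integer seed.
#' @return list with `image`, `mask` and `truth` (`level`, `background`).
#' @export
make_dextran_image <- function(level = 100, background = 10, noise_sd = 2,
                               size = 128, seed = 1L) {
  c0 <- (size + 1) / 2
  gx <- outer(seq_len(size), rep(1, size)) - c0
  gy <- outer(rep(1, size), seq_len(size)) - c0
  mask <- matrix(as.integer(sqrt(gx^2 + gy^2) <= 0.4 * size), size, size)
  img <- background + level * mask
  img <- img + .with_seed(seed, stats::rnorm(length(img), 0, noise_sd))
  list(image = matrix(img, size, size), mask = mask,
       truth = list(level = level, background = background))
}
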