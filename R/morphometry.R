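# Morphometry on segmented central-z-plane images: nuclear aspect ratios by
# zone, marker-positive fractions, invasive/core areas, and
# background-subtracted region intensities. Segmentation itself is out of
# scope; all operations consume label or mask images.

#' Per-nucleus shape descriptors from a label image
#'
#' Computes the moment-equivalent ellipse of each labelled object and
#' reports major/minor axis lengths and their ratio. Objects smaller than
#' `min_area` are dropped (count reported as an attribute); objects with a
#' degenerate (zero) minor axis are flagged invalid and excluded.
#'
#' @param labels 2D integer label matrix, 0 = background.
#' @param intensity optional intensity matrix of the same size; adds a
#'   per-object `mean_intensity` column.
#' @param min_area minimum object area in pixels (default 20).
#' @return data.frame with columns `label`, `cx`, `cy`, `area`,
#'   `major_axis`, `minor_axis`, `aspect_ratio`, optionally
#'   `mean_intensity`, and `zone` (NA until [classify_zone()]). Attributes
#'   `n_dropped_small` and `n_dropped_degenerate` count exclusions.
#' @export
nucleus_shapes <- function(labels, intensity = NULL, min_area = 20) {
  stopifnot(is.matrix(labels))
  if (max(labels) < 1) stop("label image contains no objects",
                            call. = FALSE)
  if (!is.null(intensity)) stopifnot(all(dim(intensity) == dim(labels)))
  mom <- EBImage::computeFeatures.moment(labels)
  shp <- EBImage::computeFeatures.shape(labels)
  ids <- sort(unique(labels[labels > 0]))
  major <- mom[, "m.majoraxis"]
  ecc <- mom[, "m.eccentricity"]
  minor <- major * sqrt(pmax(1 - ecc^2, 0))
  df <- data.frame(label = ids, cx = mom[, "m.cx"], cy = mom[, "m.cy"],
                   area = shp[, "s.area"], major_axis = major,
                   minor_axis = minor,
                   aspect_ratio = ifelse(minor > 0, major / minor, NA))
  if (!is.null(intensity)) {
    mi <- tapply(intensity[labels > 0], labels[labels > 0], mean)
    df$mean_intensity <- as.numeric(mi[as.character(ids)])
  }
  df$zone <- NA_character_
  degenerate <- !is.finite(df$aspect_ratio) | df$minor_axis <= 0
  small <- df$area < min_area
  out <- df[!degenerate & !small, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_small") <- sum(small & !degenerate)
  attr(out, "n_dropped_degenerate") <- sum(degenerate)
  out
}

#' Assign nuclei to the spheroid center or periphery
#'
#' A nucleus is peripheral when its centroid lies within `band` pixels of
#' the spheroid boundary (Euclidean distance transform of the mask),
#' central otherwise. The default band is the median nuclear major axis of
#' the image.
#'
#' @param shapes data.frame from [nucleus_shapes()].
#' @param spheroid_mask binary matrix (1 inside the spheroid outline).
#' @param band periphery band width in pixels.
#' @return `shapes` with the `zone` column filled.
#' @export
classify_zone <- function(shapes, spheroid_mask, band = NULL) {
  stopifnot(is.matrix(spheroid_mask))
  if (is.null(band)) band <- stats::median(shapes$major_axis)
  dm <- EBImage::distmap(spheroid_mask > 0)
  ix <- pmin(pmax(round(shapes$cx), 1), nrow(spheroid_mask))
  iy <- pmin(pmax(round(shapes$cy), 1), ncol(spheroid_mask))
  d <- dm[cbind(ix, iy)]
  outside <- d <= 0
  if (any(outside)) {
    stop("centroid(s) outside the spheroid mask for label(s): ",
         paste(shapes$label[outside], collapse = ", "), call. = FALSE)
  }
  # distmap counts the boundary pixel itself as distance 1
  shapes$zone <- ifelse(d - 1 <= band, "periphery", "center")
  shapes
}

#' Fraction of marker-positive nuclei under a normalized threshold
#'
#' Nuclear intensities are normalized to the mean of a secondary-antibody
#' control distribution; a nucleus is positive when its normalized
#' intensity exceeds the control mean plus `k_sd` control standard
#' deviations.
#'
#' @param shapes data.frame with a `mean_intensity` column.
#' @param control_intensities numeric vector from secondary-only controls.
#' @param k_sd threshold stringency in control SD units (default 2).
#' @return list of class `positive_fraction_result`: `n_total`,
#'   `n_positive`, `fraction`, `threshold` (normalized units).
#' @export
positive_fraction <- function(shapes, control_intensities, k_sd = 2) {
  if (is.null(shapes$mean_intensity) || anyNA(shapes$mean_intensity)) {
    stop("shapes must carry mean_intensity for every nucleus",
         call. = FALSE)
  }
  if (length(control_intensities) == 0) {
    stop("empty control intensity set: cannot normalize", call. = FALSE)
  }
  norm <- mean(control_intensities)
  ctrl <- control_intensities / norm
  thr <- mean(ctrl) + k_sd * stats::sd(ctrl)
  vals <- shapes$mean_intensity / norm
  n_pos <- sum(vals > thr)
  structure(list(n_total = nrow(shapes), n_positive = n_pos,
                 fraction = n_pos / nrow(shapes), threshold = thr),
            class = "positive_fraction_result")
}

#' Invasive-to-core area ratio of a spheroid
#'
#' @param core_mask binary matrix tracing the compact spheroid core.
#' @param total_mask binary matrix tracing the full outline including
#'   invasive protrusions.
#' @return list of class `invasion_result`: `core_area`, `invasive_area`
#'   (total minus core, pixels^2) and their `ratio`.
#' @export
invasion_ratio <- function(core_mask, total_mask) {
  stopifnot(is.matrix(core_mask), is.matrix(total_mask),
            all(dim(core_mask) == dim(total_mask)))
  core <- core_mask > 0
  total <- total_mask > 0
  stray <- sum(core & !total)
  if (sum(core) == 0) stop("empty core mask", call. = FALSE)
  if (stray > 0.01 * sum(core)) {
    warning(sprintf("core extends outside total mask by %d px (> 1%%)",
                    stray))
  }
  core <- core & total
  core_area <- sum(core)
  if (core_area == 0) stop("empty core mask after intersection",
                           call. = FALSE)
  invasive_area <- sum(total) - core_area
  structure(list(core_area = core_area, invasive_area = invasive_area,
                 ratio = invasive_area / core_area),
            class = "invasion_result")
}

#' Background-subtracted mean intensity over a region
#'
#' @param image intensity matrix.
#' @param mask binary matrix selecting the region.
#' @param background scalar background level, or a background image whose
#'   mean over the mask is subtracted.
#' @return the background-subtracted mean intensity.
#' @export
region_mean_intensity <- function(image, mask, background = 0) {
  stopifnot(is.matrix(image), is.matrix(mask),
            all(dim(image) == dim(mask)))
  sel <- mask > 0
  if (!any(sel)) stop("empty region mask", call. = FALSE)
  bg <- if (is.matrix(background)) mean(background[sel]) else background
  mean(image[sel]) - bg
}
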