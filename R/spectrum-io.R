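#' Construct a spectrum object
#'
#' A spectrum is the universal I/O unit of the package: one spectral axis
#' plus one intensity trace. Brillouin spectra carry frequency in GHz (and
#' may span negative and positive frequencies around the elastic line);
#' Raman spectra carry the Raman shift in cm^-1. Units are declared by
#' `kind`, never inferred from the axis range, because GHz and cm^-1 axes
#' can numerically overlap.
#'
#' @param axis numeric, strictly increasing spectral axis (GHz or cm^-1).
#' @param intensity numeric, non-negative intensities, same length as `axis`.
#'   Intensities that have been background- or reference-subtracted may be
#'   negative; validation only forbids negative values on raw spectra when
#'   `check_nonneg = TRUE`.
#' @param kind `"brillouin"` or `"raman"`.
#' @param meta named list of free-form metadata (sample id, objective,
#'   condition, time bin, ...).
#' @param min_points minimum number of points (default 16); lower it only
#'   for deliberately tiny fixtures.
#' @param check_nonneg require non-negative intensities (default FALSE so
#'   subtracted residual spectra remain representable).
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(axis, intensity, kind = c("brillouin", "raman"),
                     meta = list(), min_points = 16L, check_nonneg = FALSE) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have the same length", call. = FALSE)
  }
  if (length(axis) < min_points) {
    stop(sprintf("spectrum has %d points; at least %d required",
                 length(axis), min_points), call. = FALSE)
  }
  if (anyNA(axis) || anyNA(intensity)) {
    stop("spectrum contains missing values", call. = FALSE)
  }
  ord <- order(axis)
  axis <- axis[ord]
  intensity <- intensity[ord]
  if (any(diff(axis) <= 0)) {
    stop("spectral axis must be strictly increasing (duplicate axis values?)",
         call. = FALSE)
  }
  if (check_nonneg && any(intensity < 0)) {
    stop("negative intensities in a raw spectrum", call. = FALSE)
  }
  structure(list(axis = axis, intensity = intensity, kind = kind,
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$kind == "brillouin") "GHz" else "cm^-1"
  cat(sprintf("<%s spectrum> %d points, axis %.4g..%.4g %s\n",
              x$kind, length(x$axis), min(x$axis), max(x$axis), unit))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a spectrum from two-column delimited text
#'
#' The on-disk dialect is two numeric columns (axis, intensity) separated by
#' whitespace or commas, with optional `#`-prefixed comment lines. Header
#' comments of the form `# key: value` are parsed into the spectrum's
#' metadata.
#'
#' @param path file path.
#' @inheritParams spectrum
#' @return a [spectrum].
#' @export
read_spectrum <- function(path, kind = c("brillouin", "raman"),
                          min_points = 16L) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cl))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(data_lines) == 0) {
    stop("no data rows in ", path, call. = FALSE)
  }
  parsed <- lapply(seq_along(data_lines), function(i) {
    fields <- strsplit(trimws(data_lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop(sprintf("non-numeric data at line %d of %s: '%s'",
                   which(!is_comment & nzchar(trimws(lines)))[i], path,
                   data_lines[i]), call. = FALSE)
    }
    vals[1:2]
  })
  mat <- do.call(rbind, parsed)
  spectrum(mat[, 1], mat[, 2], kind = kind, meta = meta,
           min_points = min_points)
}

#' Write a spectrum to two-column delimited text
#'
#' Metadata are emitted as `# key: value` header comments so a round trip
#' through [read_spectrum()] preserves them. Axis and intensity are written
#' at full double precision (17 significant digits) so the round trip is
#' lossless.
#'
#' @param spec a [spectrum].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  if (length(spec$intensity) == 0) {
    stop("refusing to write an empty spectrum", call. = FALSE)
  }
  header <- c(sprintf("# kind: %s", spec$kind),
              vapply(names(spec$meta),
                     function(k) sprintf("# %s: %s", k, spec$meta[[k]]),
                     character(1)))
  body <- sprintf("%.17g %.17g", spec$axis, spec$intensity)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

.conditions <- c("control", "rock", "rhoa", "compressed", "flow",
                 "cycle1", "cycle4")
.objectives <- c("20x", "60x")

#' Read a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `condition`, `objective`,
#' `time_bin_min`, `brillouin_path`, `raman_path`, `image_path` (path
#' columns may be empty per modality). Conditions and objectives are
#' validated against the experimental design vocabulary; relative paths are
#' resolved against the manifest's directory and, when `check_files` is
#' TRUE, required to exist.
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced files exist (default TRUE).
#' @return a data.frame with one row per sample, class `sample_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("sample_id", "condition", "objective", "time_bin_min",
                "brillouin_path", "raman_path", "image_path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_cond <- setdiff(unique(df$condition), .conditions)
  if (length(bad_cond)) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         "; allowed: ", paste(.conditions, collapse = ", "), call. = FALSE)
  }
  bad_obj <- setdiff(unique(df$objective), .objectives)
  if (length(bad_obj)) {
    stop("unknown objective label(s): ", paste(bad_obj, collapse = ", "),
         "; allowed: ", paste(.objectives, collapse = ", "), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  for (col in if (nrow(df)) c("brillouin_path", "raman_path",
                              "image_path") else character(0)) {
    nonempty <- nzchar(df[[col]])
    resolved <- ifelse(nonempty & !grepl("^/", df[[col]]),
                       file.path(base, df[[col]]), df[[col]])
    if (check_files) {
      gone <- nonempty & !file.exists(resolved)
      if (any(gone)) {
        stop("manifest references missing file(s): ",
             paste(resolved[gone], collapse = ", "), call. = FALSE)
      }
    }
    df[[col]] <- resolved
  }
  class(df) <- c("sample_manifest", class(df))
  df
}

#' Read a single-plane image from TIFF
#'
#' Label images (integer object ids, 0 = background) and binary masks are
#' exchanged as single-plane 16-bit TIFFs. Values are restored to their
#' integer scale on read.
#'
#' @param path TIFF path.
#' @return an integer matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) > 2) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow = nrow(img))
}

#' Write a single-plane integer image to TIFF
#'
#' @param img integer matrix with values in 0..65535.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  if (max(img) > 65535 || min(img) < 0) {
    stop("image values must lie in 0..65535 for 16-bit TIFF", call. = FALSE)
  }
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
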