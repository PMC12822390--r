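# Write a complete synthetic dataset (spectra, references, ground-truth
# sidecars, manifest) to disk so the whole pipeline is file-testable.

#' Generate a synthetic multi-condition dataset on disk
#'
#' For each condition and replicate, writes a Brillouin spectrum, a Raman
#' spectrum and a ground-truth JSON sidecar; one shared reference set and a
#' manifest loadable by [read_manifest()] tie the tree together. Per-sample
#' seeds are derived deterministically from the master seed, so two runs
#' with the same seed produce byte-identical trees.
#'
#' @param conditions character vector of condition names.
#' @param n_per replicates per condition.
#' @param seed master seed.
#' @param outdir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param noiseless generate noiseless spectra.
#' @param presets optional named list of [condition_preset] overrides.
#' @return the manifest path, invisibly.
#' @export
make_dataset <- function(conditions = c("control", "rock"), n_per = 5,
                         seed = 1L, outdir, overwrite = FALSE,
                         noiseless = FALSE, presets = NULL) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty; pass overwrite = TRUE",
         call. = FALSE)
  }
  for (d in c("spectra", "refs", "truth")) {
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  }
  refs <- make_reference_set(seed = .child_seed(seed, 0))
  for (role in c("pdms", "medium", "offchip")) {
    write_spectrum(refs[[role]],
                   file.path(outdir, "refs", paste0(role, ".txt")))
  }
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    preset <- if (!is.null(presets) && !is.null(presets[[cond]])) {
      presets[[cond]]
    } else {
      condition_preset(cond)
    }
    for (i in seq_len(n_per)) {
      sid <- sprintf("%s_%02d", cond, i)
      bseed <- .child_seed(seed, ci, i, 1)
      rseed <- .child_seed(seed, ci, i, 2)
      br <- make_brillouin(preset, seed = bseed, noiseless = noiseless)
      rm_ <- make_raman(preset, seed = rseed, noiseless = noiseless)
      bpath <- file.path("spectra", paste0(sid, "_brillouin.txt"))
      rpath <- file.path("spectra", paste0(sid, "_raman.txt"))
      write_spectrum(br$spectrum, file.path(outdir, bpath))
      write_spectrum(rm_$spectrum, file.path(outdir, rpath))
      truth <- list(sample_id = sid, brillouin = br$truth,
                    raman = rm_$truth)
      jsonlite::write_json(truth,
                           file.path(outdir, "truth", paste0(sid, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, condition = cond, objective = "20x",
        time_bin_min = "", brillouin_path = bpath, raman_path = rpath,
        image_path = "", stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
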