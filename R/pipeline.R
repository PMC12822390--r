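# Orchestration: batch processing of a sample manifest and the group
# comparison reporting layer.

#' Assemble a pipeline configuration
#'
#' Every stage parameter has a default; the effective configuration is
#' echoed into the output directory by [run_pipeline()] so a run can be
#' reproduced from its results alone.
#'
#' @param manifest_path sample manifest CSV.
#' @param pdms_path,medium_path,offchip_path Raman reference spectra.
#' @param outdir results directory.
#' @param exclusion elastic-line exclusion half-width, GHz.
#' @param ch_window,oh_window Raman band windows, cm^-1.
#' @param knot_spacing baseline spline knot spacing, cm^-1.
#' @param anchor_regions baseline anchor windows.
#' @param k_sd marker-positive threshold stringency.
#' @param band periphery band width, pixels (NULL = median major axis).
#' @param phi_min mixture-inversion conditioning guard.
#' @param kappa calibrated efficiency constant; when NULL it is calibrated
#'   from the manifest's compressed samples (known Phi_ECM = 0).
#' @param w_cell,w_ecm biphasic model water fractions.
#' @param seed master seed for any seeded sub-step.
#' @param normalize_by manifest column used as the batch key when
#'   normalizing shifts to controls.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest_path, pdms_path, medium_path,
                            offchip_path, outdir, exclusion = 2,
                            ch_window = c(2800, 3020),
                            oh_window = c(3020, 3700), knot_spacing = 50,
                            anchor_regions = list(c(2600, 2750),
                                                  c(3750, 3900)),
                            k_sd = 2, band = NULL, phi_min = 0.02,
                            kappa = NULL, w_cell = 0.70, w_ecm = 1.0,
                            seed = 1L, normalize_by = "objective") {
  structure(list(manifest_path = manifest_path, pdms_path = pdms_path,
                 medium_path = medium_path, offchip_path = offchip_path,
                 outdir = outdir, exclusion = exclusion,
                 ch_window = ch_window, oh_window = oh_window,
                 knot_spacing = knot_spacing,
                 anchor_regions = anchor_regions, k_sd = k_sd, band = band,
                 phi_min = phi_min, kappa = kappa, w_cell = w_cell,
                 w_ecm = w_ecm, seed = seed, normalize_by = normalize_by),
            class = "pipeline_config")
}

#' Run the full analysis over a sample manifest
#'
#' For each sample: DHO-fit the Brillouin spectrum (with symmetry
#' recentering) and run the Raman CH/OH chain; then estimate the biphasic
#' composition of every sample with a Raman result, calibrating kappa from
#' the manifest's compressed samples when not supplied. Per-sample failures
#' are recorded and do not abort the run; only manifest-level errors do.
#' Writes `brillouin.csv`, `raman.csv`, `composition.csv`, a per-condition
#' `summary.csv` and a `config.yaml` echo into the output directory.
#'
#' @param config a [pipeline_config].
#' @return the output directory, invisibly; per-sample tables are also
#'   returned as the attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(config$manifest_path)
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  refs <- raman_references(
    pdms = read_spectrum(config$pdms_path, "raman"),
    medium = read_spectrum(config$medium_path, "raman"),
    offchip = read_spectrum(config$offchip_path, "raman"))
  windows <- band_windows(config$ch_window, config$oh_window)

  brill <- list()
  raman <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (nzchar(row$brillouin_path)) {
      brill[[row$sample_id]] <- tryCatch({
        fit <- fit_brillouin(read_spectrum(row$brillouin_path, "brillouin"),
                             exclusion = config$exclusion)
        data.frame(sample_id = row$sample_id, condition = row$condition,
                   objective = row$objective, omega_b = fit$omega_b,
                   gamma = fit$gamma, se_omega = fit$se_omega,
                   se_gamma = fit$se_gamma,
                   recenter_offset = fit$recenter_offset, rss = fit$rss,
                   status = "ok")
      }, error = function(e) {
        data.frame(sample_id = row$sample_id, condition = row$condition,
                   objective = row$objective, omega_b = NA, gamma = NA,
                   se_omega = NA, se_gamma = NA, recenter_offset = NA,
                   rss = NA, status = conditionMessage(e))
      })
    }
    if (nzchar(row$raman_path)) {
      raman[[row$sample_id]] <- tryCatch({
        rr <- ch_oh_ratio(read_spectrum(row$raman_path, "raman"), refs,
                          windows, knot_spacing = config$knot_spacing,
                          anchor_regions = config$anchor_regions,
                          seed = config$seed)
        data.frame(sample_id = row$sample_id, condition = row$condition,
                   a_ch = rr$a_ch, a_oh = rr$a_oh, ratio = rr$ratio,
                   alpha_pdms = rr$alpha_pdms,
                   alpha_medium = rr$alpha_medium, status = "ok")
      }, error = function(e) {
        data.frame(sample_id = row$sample_id, condition = row$condition,
                   a_ch = NA, a_oh = NA, ratio = NA, alpha_pdms = NA,
                   alpha_medium = NA, status = conditionMessage(e))
      })
    }
  }
  brill_df <- if (length(brill)) do.call(rbind, brill) else NULL
  raman_df <- if (length(raman)) do.call(rbind, raman) else NULL

  comp_df <- NULL
  if (!is.null(raman_df) && any(raman_df$status == "ok")) {
    model <- composition_model(w_cell = config$w_cell, w_ecm = config$w_ecm)
    if (is.null(config$kappa)) {
      cal <- raman_df$condition == "compressed" & raman_df$status == "ok"
      if (!any(cal)) {
        warning("no kappa supplied and no compressed samples to calibrate ",
                "from: skipping composition estimates")
      } else {
        model <- calibrate_kappa(mean(raman_df$ratio[cal]), 0, model)
      }
    } else {
      model$kappa <- config$kappa
    }
    if (!is.na(model$kappa)) {
      ok <- raman_df$status == "ok"
      comp_rows <- lapply(which(ok), function(i) {
        est <- tryCatch(
          suppressWarnings(estimate_phi(raman_df$ratio[i], model)),
          error = function(e) NULL)
        data.frame(sample_id = raman_df$sample_id[i],
                   condition = raman_df$condition[i],
                   phi_ecm = if (is.null(est)) NA else est$phi_ecm,
                   phi_cell = if (is.null(est)) NA else est$phi_cell)
      })
      comp_df <- do.call(rbind, comp_rows)
      comp_df$kappa <- model$kappa
    }
  }

  if (!is.null(brill_df)) {
    norm <- tryCatch(
      normalize_to_controls(brill_df$omega_b, brill_df$condition,
                            brill_df[[config$normalize_by]]),
      error = function(e) rep(NA_real_, nrow(brill_df)))
    brill_df$omega_b_normalized <- norm
  }

  summarise <- function(df, value, label) {
    ok <- !is.na(df[[value]])
    if (!any(ok)) return(NULL)
    agg <- stats::aggregate(df[[value]][ok],
                            by = list(condition = df$condition[ok]),
                            function(v) c(n = length(v), mean = mean(v),
                                          sd = stats::sd(v)))
    out <- data.frame(condition = agg$condition, metric = label,
                      n = agg$x[, "n"], mean = agg$x[, "mean"],
                      sd = agg$x[, "sd"])
    out
  }
  summary_df <- rbind(
    if (!is.null(brill_df)) summarise(brill_df, "omega_b", "omega_b"),
    if (!is.null(brill_df)) summarise(brill_df, "omega_b_normalized",
                                      "omega_b_normalized"),
    if (!is.null(raman_df)) summarise(raman_df, "ratio", "ch_oh_ratio"),
    if (!is.null(comp_df)) summarise(comp_df, "phi_ecm", "phi_ecm"))

  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(config$outdir, name),
                       row.names = FALSE)
    }
  }
  wr(brill_df, "brillouin.csv")
  wr(raman_df, "raman.csv")
  wr(comp_df, "composition.csv")
  wr(summary_df, "summary.csv")
  echo <- unclass(config)
  echo$package_version <- as.character(utils::packageVersion("brmspheroid"))
  yaml::write_yaml(echo, file.path(config$outdir, "config.yaml"))
  out <- config$outdir
  attr(out, "results") <- list(brillouin = brill_df, raman = raman_df,
                               composition = comp_df, summary = summary_df)
  invisible(out)
}

#' Compare measurement groups with the normality-gated test battery
#'
#' Two groups: Shapiro-Wilk normality gate (alpha 0.05) selects an unpaired
#' two-tailed Student's t-test (both groups normal) or a Mann-Whitney test.
#' More than two groups: ordinary one-way ANOVA followed by Tukey's
#' all-pairs comparison, or Dunnett's comparisons against the control when
#' `design = "vs_control"`.
#'
#' @param values named list of numeric vectors, one per group (n >= 3
#'   each).
#' @param design `"auto"` (pairwise for 2 groups, all-pairs otherwise),
#'   `"all_pairs"` (Tukey) or `"vs_control"` (Dunnett).
#' @param control control group name for the Dunnett design (default
#'   "control" if present, else the first group).
#' @param alpha normality-gate significance level.
#' @return list of class `group_comparison`: per-group summary, test name,
#'   gate result, p-value(s) and effect direction.
#' @export
compare_groups <- function(values, design = c("auto", "all_pairs",
                                              "vs_control"),
                           control = NULL, alpha = 0.05) {
  design <- match.arg(design)
  if (!is.list(values) || length(values) < 2 || is.null(names(values))) {
    stop("values must be a named list of at least two groups",
         call. = FALSE)
  }
  n <- vapply(values, length, integer(1))
  if (any(n < 3)) {
    stop("each group needs at least 3 observations; got: ",
         paste(sprintf("%s=%d", names(values), n), collapse = ", "),
         call. = FALSE)
  }
  summary_df <- data.frame(group = names(values), n = n,
                           mean = vapply(values, mean, numeric(1)),
                           sd = vapply(values, stats::sd, numeric(1)))
  # Shapiro-Wilk is defined for 3 <= n <= 5000 and non-degenerate samples.
  sw_p <- vapply(values, function(v) {
    if (stats::sd(v) == 0) return(0)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  all_normal <- all(sw_p > alpha)

  if (length(values) == 2) {
    g1 <- values[[1]]
    g2 <- values[[2]]
    if (all_normal) {
      ht <- stats::t.test(g1, g2, var.equal = TRUE)
      test <- "t-test"
    } else {
      ht <- stats::wilcox.test(g1, g2, exact = FALSE)
      test <- "Mann-Whitney"
    }
    res <- structure(list(summary = summary_df, test = test,
                          normality_p = sw_p, all_normal = all_normal,
                          p_value = ht$p.value,
                          direction = sign(mean(g1) - mean(g2))),
                     class = "group_comparison")
    return(res)
  }

  df <- data.frame(value = unlist(values),
                   group = factor(rep(names(values), n)))
  if (design == "vs_control") {
    if (is.null(control)) {
      control <- if ("control" %in% names(values)) "control"
                 else names(values)[1]
    }
    df$group <- stats::relevel(df$group, ref = control)
    fit <- stats::aov(value ~ group, data = df)
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(glht_fit)
    pvals <- as.numeric(sm$test$pvalues)
    names(pvals) <- names(sm$test$coefficients)
    test <- "ANOVA+Dunnett"
    est <- as.numeric(sm$test$coefficients)
  } else {
    fit <- stats::aov(value ~ group, data = df)
    tk <- stats::TukeyHSD(fit)$group
    pvals <- tk[, "p adj"]
    test <- "ANOVA+Tukey"
    est <- tk[, "diff"]
  }
  structure(list(summary = summary_df, test = test, normality_p = sw_p,
                 all_normal = all_normal, p_value = pvals,
                 anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
                 direction = sign(est)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group comparison> %s\n", x$test))
  print(x$summary, row.names = FALSE)
  cat("p-value(s):\n")
  print(x$p_value)
  invisible(x)
}
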