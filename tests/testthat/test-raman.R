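test_that("resampling interpolates linearly and conserves band areas", {
  sp <- spectrum(seq(2400, 4000, by = 2), seq_len(801), "raman")
  same <- resample_to(sp, sp$axis)
  expect_equal(same$intensity, sp$intensity)

  mids <- sp$axis[-1] - 1
  rs <- resample_to(sp, mids)
  expect_equal(rs$intensity, seq_len(800) + 0.5)

  # Gaussian band resampled to double density keeps its area
  x <- seq(2400, 4000, by = 4)
  g <- spectrum(x, exp(-(x - 3000)^2 / (2 * 60^2)), "raman")
  dense <- resample_to(g, seq(2400, 4000, by = 2))
  a1 <- integrate_band(g, c(2700, 3300))
  a2 <- integrate_band(dense, c(2700, 3300))
  expect_lt(abs(a2 / a1 - 1), 0.001)

  expect_error(resample_to(g, seq(2000, 4000, by = 4)), "extrapolation")
})

test_that("band integration matches closed forms", {
  x <- seq(2400, 4000, by = 1)
  rect <- spectrum(x, as.numeric(x >= 2950 & x <= 3050), "raman")
  # trapezoid over the sampled indicator: 100 interior + two half edges
  expect_equal(integrate_band(rect, c(2900, 3100)), 101)

  gauss <- spectrum(x, exp(-(x - 3000)^2 / (2 * 30^2)), "raman")
  expect_lt(abs(integrate_band(gauss, c(2800, 3200)) -
                  30 * sqrt(2 * pi)), 0.5)

  zero <- spectrum(x, rep(0, length(x)), "raman")
  expect_equal(integrate_band(zero, c(2800, 3200)), 0)
  expect_error(integrate_band(gauss, c(2000, 2500)), "outside")
})

test_that("spline baseline removal recovers band areas under fluorescence", {
  pc <- condition_preset("control")
  flat <- condition_preset("control", baseline_coeffs = c(0, 0, 0, 0))
  clean <- make_raman(flat, seed = 1, with_pdms = FALSE, with_medium = FALSE,
                      noiseless = TRUE)$spectrum
  # baseline-free input passes through almost unchanged
  bl0 <- remove_baseline(clean)
  for (win in list(test_windows$ch, test_windows$oh)) {
    a_in <- integrate_band(clean, win)
    a_out <- integrate_band(bl0$corrected, win)
    expect_lt(abs(a_out / a_in - 1), 0.01)
  }

  # cubic fluorescence pedestal is removed to within 2% of band areas
  gen <- make_raman(pc, seed = 1, with_pdms = FALSE, with_medium = FALSE,
                    noiseless = TRUE)
  bl <- remove_baseline(gen$spectrum)
  for (win in list(test_windows$ch, test_windows$oh)) {
    a_truth <- integrate_band(clean, win)
    a_corr <- integrate_band(bl$corrected, win)
    expect_lt(abs(a_corr / a_truth - 1), 0.02)
  }

  expect_error(remove_baseline(clean, anchor_regions = list(c(2600, 2602))),
               "fewer than 3")
  expect_error(remove_baseline(clean, anchor_regions = list(c(2900, 3000)),
                               windows = test_windows), "overlaps")
})

test_that("scaled reference subtraction is exact", {
  flat <- condition_preset("control", baseline_coeffs = c(0, 0, 0, 0))
  cell <- make_raman(flat, seed = 1, with_pdms = FALSE, with_medium = FALSE,
                     noiseless = TRUE)
  composite <- cell$spectrum
  composite$intensity <- composite$intensity +
    0.3 * test_refs$pdms$intensity
  out <- subtract_scaled(composite, test_refs$pdms, 0.3)
  expect_equal(out$intensity, cell$spectrum$intensity, tolerance = 1e-12)

  ident <- subtract_scaled(composite, test_refs$pdms, 0)
  expect_equal(ident$intensity, composite$intensity)

  # exact cancellation
  zero <- subtract_scaled(
    spectrum(test_refs$pdms$axis, 0.7 * test_refs$pdms$intensity, "raman"),
    test_refs$pdms, 0.7)
  expect_true(all(abs(zero$intensity) < 1e-12))

  # over-subtraction flags a negative integrated residual
  over <- subtract_scaled(
    spectrum(test_refs$pdms$axis, 0.7 * test_refs$pdms$intensity, "raman"),
    test_refs$pdms, 1.5)
  expect_true(isTRUE(over$meta$negative_integral))

  off <- test_refs$pdms
  off$axis <- off$axis + 0.5
  expect_error(subtract_scaled(composite, off, 1), "same axis")
})

test_that("subtraction factors are recovered on contaminated composites", {
  pc <- condition_preset("control", pdms_level = 0.20, medium_level = 0.50)
  gen <- make_raman(pc, seed = 2, noiseless = TRUE)
  res <- ch_oh_ratio(gen$spectrum, test_refs, test_windows)
  expect_lt(abs(res$alpha_pdms - gen$truth$alpha_pdms_true), 0.01)
  expect_lt(abs(res$alpha_medium - gen$truth$alpha_medium_true), 0.01)

  # no chip contamination: the PDMS factor collapses to zero, and the
  # medium factor carries only the spheroid's own water amplitude
  gen0 <- make_raman(pc, seed = 2, with_pdms = FALSE, with_medium = FALSE,
                     noiseless = TRUE)
  res0 <- ch_oh_ratio(gen0$spectrum, test_refs, test_windows)
  expect_lte(res0$alpha_pdms, 0.02)
  expect_lt(abs(res0$alpha_medium - gen0$truth$alpha_medium_true), 0.01)
})

test_that("the CH/OH ratio tracks composition and is scale invariant", {
  pc <- condition_preset("control")
  gen <- make_raman(pc, seed = 1, with_pdms = FALSE, with_medium = FALSE,
                    noiseless = TRUE)
  res <- ch_oh_ratio(gen$spectrum, test_refs, test_windows)
  expect_lt(abs(res$ratio / gen$truth$ratio_analytic - 1), 0.02)

  # global intensity rescaling (sample and references together)
  scaled <- gen$spectrum
  scaled$intensity <- scaled$intensity * 2
  refs2 <- test_refs
  for (k in c("pdms", "medium", "offchip")) {
    refs2[[k]]$intensity <- refs2[[k]]$intensity * 2
  }
  res2 <- ch_oh_ratio(scaled, refs2, test_windows)
  expect_lt(abs(res2$ratio / res$ratio - 1), 1e-9)

  # pure-water sample: CH band area at the noise floor
  water <- spectrum(test_refs$medium$axis,
                    test_refs$medium$intensity +
                      0.5 * max(test_refs$medium$intensity),
                    "raman")
  resw <- ch_oh_ratio(water, test_refs, test_windows)
  expect_lt(resw$ratio, 0.01)
})

test_that("the ratio decreases monotonically with ECM water fraction", {
  phis <- seq(0, 0.5, length.out = 11)
  ratios <- vapply(phis, function(p) {
    gen <- make_raman(condition_preset("control", phi_ecm = p), seed = 1,
                      with_pdms = FALSE, with_medium = FALSE,
                      noiseless = TRUE)
    ch_oh_ratio(gen$spectrum, test_refs, test_windows)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("re-running the subtraction chain is idempotent within 1%", {
  pc <- condition_preset("control")
  gen <- make_raman(pc, seed = 3, noiseless = TRUE)
  res <- ch_oh_ratio(gen$spectrum, test_refs, test_windows)
  # feed the PDMS-subtracted, baseline-corrected spectrum back through
  bl <- remove_baseline(gen$spectrum, windows = test_windows)
  processed <- subtract_scaled(bl$corrected,
                               resample_to(test_refs$pdms, bl$corrected$axis),
                               res$alpha_pdms)
  res2 <- ch_oh_ratio(processed, test_refs, test_windows)
  expect_lt(abs(res2$ratio / res$ratio - 1), 0.01)
})
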