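test_that("kappa calibration has the expected closed form and guards", {
  model <- calibrate_kappa(0.30, 0, composition_model(w_cell = 0.70))
  expect_equal(model$kappa, 0.30 * 7 / 3, tolerance = 1e-12)
  expect_error(calibrate_kappa(0.30, 1), "undefined")

  # round trip through the model ratio at a nonzero reference fraction
  m0 <- composition_model(kappa = 0.7)
  r_at <- function(phi, m) {
    m$kappa * m$d_cell * (1 - phi) /
      (m$w_cell * (1 - phi) + m$w_ecm * phi)
  }
  m1 <- calibrate_kappa(r_at(0.15, m0), 0.15, composition_model())
  expect_lt(abs(m1$kappa - 0.7), 1e-9)
})

test_that("phi estimation hits its closed-form limits and propagates error", {
  model <- composition_model(kappa = 0.7)
  # r at the pure-cell limit
  est0 <- estimate_phi(model$kappa * model$d_cell / model$w_cell, model)
  expect_equal(est0$phi_ecm, 0, tolerance = 1e-12)
  # r = 0: pure water
  est1 <- estimate_phi(0, model)
  expect_equal(est1$phi_ecm, 1)
  expect_equal(est1$phi_cell, 0)
  # slightly negative estimates clamp with a warning; gross ones error
  r_hi <- model$kappa * model$d_cell / model$w_cell * 1.02
  expect_warning(est2 <- estimate_phi(r_hi, model), "clamped")
  expect_equal(est2$phi_ecm, 0)
  expect_error(estimate_phi(10, model), "incompatible")
  expect_error(estimate_phi(-0.1, model), "non-negative")
  # uncertainty propagation is first order in the ratio SE
  e_lo <- estimate_phi(0.2, model, se_r = 0.001)
  num <- (estimate_phi(0.2005, model)$phi_ecm -
            estimate_phi(0.1995, model)$phi_ecm) / 0.001
  expect_lt(abs(e_lo$se_phi - abs(num) * 0.001) / e_lo$se_phi, 0.01)
})

test_that("composition recovery through the Raman chain is accurate", {
  # noiseless uncontaminated chain, calibrated on a compressed reference
  model <- composition_model()
  r_comp <- ch_oh_ratio(
    make_raman(condition_preset("compressed"), seed = 1, with_pdms = FALSE,
               with_medium = FALSE, noiseless = TRUE)$spectrum,
    test_refs, test_windows)
  model <- calibrate_kappa(r_comp$ratio, 0, model)
  for (phi in c(0.15, 0.24)) {
    gen <- make_raman(condition_preset("control", phi_ecm = phi), seed = 1,
                      with_pdms = FALSE, with_medium = FALSE,
                      noiseless = TRUE)
    est <- estimate_phi(ch_oh_ratio(gen$spectrum, test_refs,
                                    test_windows)$ratio, model)
    expect_lt(abs(est$phi_ecm - phi), 0.01)
    expect_equal(est$phi_ecm + est$phi_cell, 1)
  }
})

test_that("the linear mixture and its inversions are exact algebra", {
  expect_equal(forward_omega(8.20, 8.00, 0), 8.20)
  expect_equal(forward_omega(8.20, 8.00, 1), 8.00)
  expect_equal(forward_omega(8.20, 8.00, 0.15), 8.17)
  expect_equal(invert_omega_ecm(8.17, 8.20, 0.15), 8.00,
               tolerance = 1e-12)
  expect_error(forward_omega(8.2, 8.0, 1.2), "0, 1")

  set.seed(7)
  for (i in 1:100) {
    oc <- runif(1, 7, 9)
    oe <- runif(1, 7, 9)
    phi <- runif(1, 0.05, 0.95)
    ob <- forward_omega(oc, oe, phi)
    expect_lt(abs(invert_omega_ecm(ob, oc, phi) - oe), 1e-9)
    expect_lt(abs(invert_omega_cell(ob, oe, phi) - oc), 1e-9)
    # bracketing between the component shifts
    expect_gte(ob, min(oc, oe) - 1e-12)
    expect_lte(ob, max(oc, oe) + 1e-12)
  }

  expect_error(invert_omega_ecm(8.17, 8.20, 0.005), "ill-conditioned")
  expect_error(invert_omega_cell(8.17, 8.00, 0.999), "ill-conditioned")
})

test_that("phi estimation decreases monotonically in the measured ratio", {
  model <- composition_model(kappa = 0.7)
  r_max <- model$kappa * model$d_cell / model$w_cell
  rs <- seq(0.001, r_max * 0.999, length.out = 25)
  phis <- vapply(rs, function(r) estimate_phi(r, model)$phi_ecm,
                 numeric(1))
  expect_true(all(diff(phis) < 0))
})

test_that("negligible-ECM operationalization treats small fractions as zero", {
  model <- composition_model(kappa = 0.7)
  near0 <- estimate_phi(model$kappa * model$d_cell / model$w_cell * 0.995,
                        model)
  expect_true(is_negligible_ecm(near0))
  expect_false(is_negligible_ecm(0.15))
})

test_that("end-to-end recovery of composition and ECM shift at realistic noise", {
  # seeded samples spanning the physiological ECM-fraction range; the full
  # chain (raman ratio -> phi; compressed + composite DHO fits -> omega_ecm)
  # recovers the generative truth
  model <- composition_model()
  r_cal <- mean(vapply(1:10, function(s) {
    ch_oh_ratio(make_raman(condition_preset("compressed"), seed = 9000 + s,
                           with_pdms = FALSE, with_medium = FALSE)$spectrum,
                test_refs, test_windows)$ratio
  }, numeric(1)))
  model <- calibrate_kappa(r_cal, 0, model)

  set.seed(42)
  phis_true <- runif(60, 0, 0.3)
  err_phi <- numeric(length(phis_true))
  err_oe <- c()
  for (i in seq_along(phis_true)) {
    preset <- condition_preset("control", phi_ecm = phis_true[i])
    gen <- make_raman(preset, seed = 100 + i, with_pdms = FALSE,
                      with_medium = FALSE)
    est <- suppressWarnings(
      estimate_phi(ch_oh_ratio(gen$spectrum, test_refs,
                               test_windows)$ratio, model))
    err_phi[i] <- abs(est$phi_ecm - phis_true[i])
    if (est$phi_ecm >= 0.05) {
      comp_preset <- condition_preset("compressed",
                                      omega_cell = preset$omega_cell)
      f_comp <- fit_dho(make_brillouin(comp_preset,
                                       seed = 200 + i)$spectrum)
      f_mix <- fit_dho(make_brillouin(preset, seed = 300 + i)$spectrum)
      oe <- invert_omega_ecm(f_mix$omega_b, f_comp$omega_b, est$phi_ecm)
      err_oe <- c(err_oe, abs(oe - preset$omega_ecm))
    }
  }
  expect_lt(mean(err_phi), 0.02)
  expect_gt(length(err_oe), 10)
  expect_lt(mean(err_oe), 0.05)
})
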