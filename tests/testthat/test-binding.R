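test_that("corrected Stern-Volmer recovers K on noiseless static data", {
  ts <- simulate_fluorescence_titration(
    static_scenario(1, noise_rel_F = 0, noise_rel_A = 0))
  f <- stern_volmer_fit(ts, use_corrected = TRUE, refine_free_guest = TRUE)
  expect_lt(abs(f$K / 3000 - 1), 0.005)
  expect_equal(f$intercept, 1)
  expect_false(f$curvature_flag)

  # dilute-host regime: total ~ free, no refinement needed
  sc <- simulation_scenario(3000, 1e-7, canonical_guests(), eps_guest = 0,
                            noise_rel_F = 0, noise_rel_A = 0)
  ts2 <- simulate_fluorescence_titration(sc)
  f2 <- stern_volmer_fit(ts2, use_corrected = FALSE)
  expect_lt(abs(f2$K / 3000 - 1), 0.005)
})

test_that("flat intensities give zero slope and an undefined R^2", {
  pts <- data.frame(host_total = 1e-5,
                    guest_total = c(0, 1e-4, 2e-4, 3e-4),
                    F = rep(1000, 4))
  f <- stern_volmer_fit(titration_series(pts, 300, 375))
  expect_equal(f$K, 0)
  expect_true(is.na(f$r_squared))
})

test_that("fit guards its preconditions", {
  pts <- data.frame(host_total = 1e-5, guest_total = c(0, 1e-4, 2e-4),
                    F = c(1000, 900, 800))
  expect_error(stern_volmer_fit(titration_series(pts, 300, 375)),
               "at least 3 titrant points")
  pts2 <- data.frame(host_total = 1e-5,
                     guest_total = c(0, 1e-4, 2e-4, 3e-4),
                     F = c(1000, 900, 0, 700))
  expect_error(stern_volmer_fit(titration_series(pts2, 300, 375)),
               "non-positive")
})

test_that("ignoring the IFE inflates K and curves the plot upward", {
  ts <- simulate_fluorescence_titration(
    static_scenario(3, noise_rel_F = 0.01, noise_rel_A = 0.002))
  fu <- stern_volmer_fit(ts, use_corrected = FALSE)
  fc <- stern_volmer_fit(ts, use_corrected = TRUE)
  expect_gt(fu$K, fc$K)
  expect_true(fu$curvature_flag)     # 10^(dA/2) bends the uncorrected plot
  expect_false(fc$curvature_flag)

  # inflation grows monotonically with the quencher's absorbance
  K_unc <- vapply(c(0, 250, 500, 1000), function(eps) {
    tse <- simulate_fluorescence_titration(
      static_scenario(5, eps_guest = eps, noise_rel_F = 0, noise_rel_A = 0))
    stern_volmer_fit(tse, use_corrected = FALSE)$K
  }, 0)
  expect_true(all(diff(K_unc) > 0))
})

test_that("explicit truncation drops high-concentration points with a message", {
  ts <- simulate_fluorescence_titration(
    static_scenario(4, noise_rel_F = 0, noise_rel_A = 0))
  expect_message(f <- stern_volmer_fit(ts, max_points = 7), "truncating")
  expect_equal(f$points_used, 7L)
})

test_that("free-intercept option reports systematic deviation", {
  ts <- simulate_fluorescence_titration(
    static_scenario(6, noise_rel_F = 0, noise_rel_A = 0))
  ts$points$F <- ts$points$F * 0.9       # miscalibrated reference
  ts$points$F[reference_index(ts)] <- ts$points$F[reference_index(ts)] / 0.9
  f <- stern_volmer_fit(ts, use_corrected = TRUE, fix_intercept = FALSE)
  expect_gt(f$intercept, 1.05)
})

test_that("global absorbance fit recovers K and flags degeneracy", {
  wl <- seq(280, 375, by = 5)
  eps_H <- spectrum(wl, 1.5e4 * exp(-((wl - 300) / 18)^2))
  eps_G <- spectrum(wl, 4e3 * exp(-((wl - 350) / 22)^2))
  eps_HG <- spectrum(wl, spectrum_at(eps_H, wl) + spectrum_at(eps_G, wl) +
                       6e3 * exp(-((wl - 330) / 15)^2))
  sc <- simulation_scenario(50, 1e-4, seq(0, 5e-3, length.out = 10),
                            eps_host = eps_H, eps_guest = eps_G,
                            eps_complex = eps_HG,
                            noise_rel_F = 0, noise_rel_A = 0,
                            lambda_ex = 300)
  out <- simulate_absorbance_titration(sc)
  fit <- global_absorbance_fit(out$series, out$spectra, eps_H, eps_G)
  expect_lt(abs(fit$K / 50 - 1), 0.001)
  expect_true(fit$identifiable)
  expect_lt(fit$residual_rms, 1e-8)

  # eps_HG = eps_H + eps_G: the spectra carry no binding information
  sc2 <- simulation_scenario(50, 1e-4, seq(0, 5e-3, length.out = 10),
                             eps_host = eps_H, eps_guest = eps_G,
                             noise_rel_F = 0, noise_rel_A = 0,
                             lambda_ex = 300)
  out2 <- simulate_absorbance_titration(sc2)
  fit2 <- global_absorbance_fit(out2$series, out2$spectra, eps_H, eps_G)
  expect_false(fit2$identifiable)
})

test_that("global fit works from the single-wavelength A_ex column", {
  sc <- simulation_scenario(200, 1e-4, seq(0, 2e-3, length.out = 8),
                            eps_host = 5e3, eps_guest = 100,
                            eps_complex = 9e3,
                            noise_rel_F = 0, noise_rel_A = 0)
  out <- simulate_absorbance_titration(sc)
  fit <- global_absorbance_fit(out$series, eps_host = 5e3, eps_guest = 100)
  expect_lt(abs(fit$K / 200 - 1), 0.01)
})

test_that("association classification follows the policy thresholds", {
  expect_equal(classify_association(0.05, 0.01), "statistical")
  expect_equal(classify_association(3000, 150), "stable")
  expect_equal(classify_association(5, 1), "weak")
  expect_equal(classify_association(50, 40), "statistical")  # not significant
})
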