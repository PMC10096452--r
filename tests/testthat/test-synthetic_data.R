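test_that("scenario validation catches bad ground truths", {
  expect_error(simulation_scenario(-1, 1e-5, c(0, 1e-4)), "K_true")
  expect_error(simulation_scenario(10, 1e-5, c(1e-5, 1e-4)),
               "exactly one zero")
  expect_error(simulation_scenario(10, 1e-5, c(0, 1e-4),
                                   complex_emissive_fraction = 2),
               "\\[0, 1\\]")
  expect_error(simulation_scenario(10, 1e-5, c(0, 1e-4), eps_guest = -5),
               "eps_guest")
})

test_that("absorbance simulation is additive when no complex forms", {
  sc <- simulation_scenario(0, 1e-5, canonical_guests(),
                            eps_host = 2e4, eps_guest = 1000,
                            noise_rel_F = 0, noise_rel_A = 0)
  out <- simulate_absorbance_titration(sc)
  expect_equal(out$series$points$A_ex,
               2e4 * 1e-5 + 1000 * canonical_guests(), tolerance = 1e-12)
  expect_true(all(out$truth$complex == 0))
})

test_that("absorbance simulation uses the exact 1:1 speciation", {
  sc <- simulation_scenario(1e4, 1e-4, c(0, 1e-4),
                            eps_host = 100, eps_guest = 50,
                            eps_complex = 500,
                            noise_rel_F = 0, noise_rel_A = 0)
  out <- simulate_absorbance_titration(sc)
  hg <- (3 - sqrt(5)) / 2e4   # quadratic mass-balance oracle
  expect_equal(out$truth$complex[2], hg, tolerance = 1e-12)
  A_expected <- 100 * (1e-4 - hg) + 50 * (1e-4 - hg) + 500 * hg
  expect_equal(out$series$points$A_ex[2], A_expected, tolerance = 1e-12)
})

test_that("per-wavelength spectra are generated on the common grid", {
  wl <- seq(250, 350, by = 5)
  sc <- simulation_scenario(
    50, 1e-4, c(0, 5e-4, 1e-3, 2e-3),
    eps_host = spectrum(wl, 2e4 * exp(-((wl - 280) / 20)^2)),
    eps_guest = spectrum(wl, 5e3 * exp(-((wl - 320) / 25)^2)),
    noise_rel_F = 0, noise_rel_A = 0, lambda_ex = 300)
  out <- simulate_absorbance_titration(sc)
  expect_length(out$spectra, 4L)
  expect_s3_class(out$spectra[[1]], "spectrum")
  expect_equal(out$series$points$A_ex,
               vapply(out$spectra, spectrum_at, 0, wavelength = 300))
})

test_that("fluorescence simulation reproduces closed-form expectations", {
  # nothing absorbs, nothing binds -> flat intensities
  sc0 <- simulation_scenario(0, 1e-5, canonical_guests(), eps_guest = 0,
                             noise_rel_F = 0, noise_rel_A = 0)
  ts0 <- simulate_fluorescence_titration(sc0)
  expect_equal(ts0$points$F, rep(1000, 12))

  # free ~ total regime: F -> F0 / (1 + K [G]) = 1000 / 1.3 = 769.23
  sc1 <- simulation_scenario(3000, 1e-5, c(0, 5e-5, 1e-4), eps_guest = 0,
                             noise_rel_F = 0, noise_rel_A = 0)
  ts1 <- simulate_fluorescence_titration(sc1)
  expect_equal(ts1$points$F[3], 1000 / 1.3, tolerance = 0.01)
  # and exactly F0 * [H]free / Ht from the speciation oracle
  hg <- bisect_complex(3000, 1e-5, 1e-4)
  expect_equal(ts1$points$F[3], 1000 * (1e-5 - hg) / 1e-5,
               tolerance = 1e-10)

  # pure attenuation: dA = 0.2 at 0.5 cm effective path -> F0 * 10^-0.1
  sc2 <- simulation_scenario(0, 1e-5, c(0, 2e-4), eps_guest = 1000,
                             noise_rel_F = 0, noise_rel_A = 0)
  ts2 <- simulate_fluorescence_titration(sc2)
  expect_equal(ts2$points$F[2], 1000 * 10^(-0.1), tolerance = 1e-12)
})

test_that("simulations are bit-identical under the same seed", {
  a <- simulate_fluorescence_titration(static_scenario(123))
  b <- simulate_fluorescence_titration(static_scenario(123))
  expect_identical(a$points, b$points)
  d1 <- single_exp_decay(77)
  d2 <- single_exp_decay(77)
  expect_identical(d1$counts, d2$counts)
  # simulators leave the caller's RNG stream untouched
  set.seed(9); before <- runif(1)
  set.seed(9); invisible(simulate_fluorescence_titration(static_scenario(5)))
  expect_identical(runif(1), before)
})

test_that("noiseless quenched intensity decreases strictly with guest", {
  ts <- simulate_fluorescence_titration(
    static_scenario(1, noise_rel_F = 0, noise_rel_A = 0))
  expect_true(all(diff(ts$points$F) < 0))
})

test_that("Poisson decay noise has variance ~ mean", {
  # essentially flat expected counts: lifetime >> record length
  ds <- decay_scenario(1, 1e9, peak_counts = 1e4, channels = 1024,
                       channel_width = 0.001, seed = 31)
  h <- simulate_decay(ds)
  mu <- decay_expected_counts(ds)
  expect_lt(abs(var(h$counts - mu) / mean(mu) - 1), 0.10)
  expect_lt(abs(mean(h$counts) / mean(mu) - 1), 0.01)
})

test_that("expected decay counts follow the model through a delta IRF", {
  ds <- decay_scenario(1, 10, peak_counts = 5e3, channels = 512,
                       channel_width = 0.05)
  mu <- decay_expected_counts(ds)
  t <- attr(mu, "channel_time")
  expect_equal(as.numeric(mu), 5e3 * exp(-t / 10), tolerance = 1e-12)
})
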