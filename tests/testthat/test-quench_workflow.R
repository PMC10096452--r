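# canonical synthetic scenarios for the sequential diagnosis
artifact_series <- function(seed) {
  simulate_fluorescence_titration(null_scenario(seed))
}
static_series <- function(seed) {
  simulate_fluorescence_titration(static_scenario(seed))
}
dynamic_series <- function(seed, K_D = 2000) {
  # collisional quenching steady state: F0/F = 1 + K_D [Q], no IFE;
  # host dilute so the static simulator's free~total isotherm has the
  # same functional form
  simulate_fluorescence_titration(
    simulation_scenario(K_D, 1e-6, canonical_guests(), eps_guest = 0,
                        seed = seed))
}
decay_set <- function(taus, seed) {
  lapply(seq_along(taus), function(i)
    simulate_decay(decay_scenario(1, taus[i], channels = 1024,
                                  channel_width = 0.05, seed = seed + i)))
}

test_that("an absorbing non-binding quencher is diagnosed as an IFE artifact", {
  r <- run_quenching_workflow(artifact_series(1))
  expect_equal(r$final_verdict, "no_quenching_ife_artifact")
  expect_equal(r$binding_class, "statistical")
  expect_equal(r$ife_assessment$verdict, "correct_required")
  expect_gt(r$sv_uncorrected$K, 1000)   # apparent binding without correction
})

test_that("static quenching with invariant lifetimes is called static", {
  qs <- c(0, 1e-4, 3e-4)
  r <- run_quenching_workflow(static_series(2),
                              decays = decay_set(rep(5, 3), 20),
                              decay_guest_totals = qs)
  expect_equal(r$final_verdict, "static_quenching")
  expect_equal(r$lifetime_verdict, "invariant")
  expect_equal(r$binding_class, "stable")
  expect_gt(r$overestimation_ratio, 1)
})

test_that("without decays, low quencher concentration permits a static call with a caveat", {
  r <- run_quenching_workflow(static_series(3))
  expect_equal(r$final_verdict, "static_quenching")
  expect_equal(r$lifetime_verdict, "not_measured")
  expect_match(paste(r$notes, collapse = " "), "caveat")
})

test_that("shortened lifetimes matching the steady state are called dynamic", {
  K_D <- 2000
  qs <- c(0, 1e-4, 3e-4)
  r <- run_quenching_workflow(dynamic_series(4, K_D),
                              decays = decay_set(5 / (1 + K_D * qs), 40),
                              decay_guest_totals = qs)
  expect_equal(r$final_verdict, "dynamic_quenching")
  expect_equal(r$lifetime_verdict, "dynamic")
})

test_that("contradictory evidence yields mixed_or_inconclusive", {
  # corrected intensities drop but lifetimes shorten far more than the
  # steady state explains: neither purely static nor consistent dynamic
  K_D <- 2000
  qs <- c(0, 1e-4, 3e-4)
  r <- run_quenching_workflow(dynamic_series(5, K_D),
                              decays = decay_set(5 / (1 + 4 * K_D * qs), 50),
                              decay_guest_totals = qs)
  expect_equal(r$final_verdict, "mixed_or_inconclusive")
})

test_that("reports are deterministic given scenario and seed", {
  r1 <- run_quenching_workflow(static_series(11))
  r2 <- run_quenching_workflow(static_series(11))
  expect_identical(workflow_summary(r1), workflow_summary(r2))
  expect_identical(capture.output(print(r1)), capture.output(print(r2)))
})

test_that("overestimation ratio is non-decreasing in the maximum delta-A", {
  dA_max <- c(0, 0.1, 0.2, 0.4)
  ratios <- vapply(dA_max, function(a) {
    sc <- simulation_scenario(3000, 1e-5, canonical_guests(),
                              eps_guest = a / 3e-4,
                              noise_rel_F = 0, noise_rel_A = 0)
    r <- run_quenching_workflow(simulate_fluorescence_titration(sc))
    r$overestimation_ratio
  }, 0)
  expect_equal(ratios[1], 1, tolerance = 1e-9)
  expect_true(all(diff(ratios) > -1e-9))
})

test_that("workflow validates its inputs", {
  expect_error(run_quenching_workflow(static_series(1), decays = list(1)),
               "decay_guest_totals")
  expect_error(geometry(cell_path_cm = 0.5, eff_excitation_path_cm = 0.9),
               "cannot exceed")
})
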