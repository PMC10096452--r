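test_that("delta-IRF convolution is the identity on the model", {
  t <- (0:511) * 0.05
  m <- decay_model(c(0.3, 0.7), c(1, 6))
  out <- convolve_with_irf(m, "delta", t)
  direct <- 0.3 * exp(-t / 1) + 0.7 * exp(-t / 6)
  expect_equal(out, direct, tolerance = 1e-12)
})

test_that("a one-channel-wide gaussian IRF approaches the delta limit", {
  t <- (0:1023) * 0.05
  m <- decay_model(1, 5)
  narrow <- convolve_with_irf(m, list(type = "gaussian", center = 0,
                                      fwhm = 0.01), t)
  direct <- exp(-t / 5)
  rel <- abs(narrow[-(1:5)] / direct[-(1:5)] - 1)
  expect_lt(max(rel), 1e-3)
})

test_that("unit-area IRF convolution conserves total counts", {
  # record length 50 lifetimes: the truncated tail is < 1e-10 relative
  t <- (0:2047) * 0.05
  m <- decay_model(1, 2)
  k <- convolve_with_irf(m, list(type = "gaussian", center = 1, fwhm = 0.4), t)
  expect_equal(sum(k), sum(exp(-t / 2)), tolerance = 1e-9)
  expect_error(convolve_with_irf(m, rep(0, length(t)), t), "IRF")
})

test_that("average lifetimes match their closed forms", {
  avg <- average_lifetimes(decay_model(c(0.5, 0.5), c(2, 8)))
  expect_equal(avg$tau_amp, 5.0)
  expect_equal(avg$tau_int, 6.8)

  one <- average_lifetimes(decay_model(3, 4.2))
  expect_equal(one$tau_amp, 4.2)
  expect_equal(one$tau_int, 4.2)

  scaled <- average_lifetimes(decay_model(c(0.5, 0.5) * 17, c(2, 8)))
  expect_equal(scaled$tau_amp, 5.0)
  expect_equal(scaled$tau_int, 6.8)
})

test_that("intensity-weighted average never falls below amplitude-weighted", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:3, 1)
    m <- decay_model(runif(n, 0.05, 1), sort(10^runif(n, -1, 1.5)))
    avg <- average_lifetimes(m)
    expect_gte(avg$tau_int, avg$tau_amp)
  }
})

test_that("reconvolution fit recovers synthetic models", {
  # single exponential, delta IRF
  f1 <- fit_multiexponential(single_exp_decay(3, tau = 5), 1)
  expect_lt(abs(f1$model$lifetimes / 5 - 1), 0.03)
  expect_gt(f1$reduced_chi_square, 0.8)
  expect_lt(f1$reduced_chi_square, 1.2)

  # two exponentials
  h2 <- simulate_decay(decay_scenario(c(0.5, 0.5), c(2, 8), channels = 1024,
                                      channel_width = 0.05, seed = 11))
  f2 <- fit_multiexponential(h2, 2)
  expect_lt(abs(f2$model$lifetimes[1] / 2 - 1), 0.05)
  expect_lt(abs(f2$model$lifetimes[2] / 8 - 1), 0.05)
  expect_gte(f2$tau_int, f2$tau_amp)

  # gaussian IRF reconvolution
  irf <- list(type = "gaussian", center = 1, fwhm = 0.5)
  h3 <- simulate_decay(decay_scenario(1, 5, irf = irf, channels = 1024,
                                      channel_width = 0.05, seed = 5))
  f3 <- fit_multiexponential(h3, 1, irf = irf)
  expect_lt(abs(f3$model$lifetimes / 5 - 1), 0.03)
})

test_that("fit recovery holds across a grid of spacings and count levels", {
  cases <- expand.grid(tau2 = c(4, 8), peak = c(3e3, 1e4))
  for (i in seq_len(nrow(cases))) {
    ds <- decay_scenario(c(0.5, 0.5), c(1.5, cases$tau2[i]),
                         peak_counts = cases$peak[i], channels = 1024,
                         channel_width = 0.05, seed = 40 + i)
    f <- fit_multiexponential(simulate_decay(ds), 2)
    expect_lt(abs(f$model$lifetimes[2] / cases$tau2[i] - 1), 0.08)
  }
})

test_that("overfitting a single-exponential decay is detectable", {
  h <- single_exp_decay(21, tau = 5)
  f2 <- tryCatch(fit_multiexponential(h, 2),
                 warning = function(w) w)
  if (inherits(f2, "warning")) {
    expect_match(conditionMessage(f2), "collapse")
  } else {
    frac <- f2$model$amplitudes / sum(f2$model$amplitudes)
    expect_lt(min(frac), 0.02)
  }
  sel <- select_n_exp(h, max_n = 2)
  expect_equal(sel$n_exp, 1L)
})

test_that("model selection finds a genuine second component", {
  h <- simulate_decay(decay_scenario(c(0.5, 0.5), c(2, 8), channels = 1024,
                                     channel_width = 0.05, seed = 13))
  expect_equal(select_n_exp(h, max_n = 2)$n_exp, 2L)
})

test_that("low-count histograms are rejected", {
  t <- (0:255) * 0.05
  h <- decay_histogram(t, rep(1L, 256))
  expect_error(fit_multiexponential(h, 1), "too few counts")
})

test_that("lifetime invariance verdicts separate static from dynamic", {
  qs <- c(0, 1e-4, 3e-4)
  fits_inv <- lapply(seq_along(qs), function(i)
    fit_multiexponential(single_exp_decay(100 + i, tau = 5), 1))
  inv <- assess_lifetime_invariance(fits_inv, qs)
  expect_equal(inv$verdict, "invariant")

  kq_tau0 <- 5000
  fits_dyn <- lapply(seq_along(qs), function(i)
    fit_multiexponential(
      single_exp_decay(200 + i, tau = 5 / (1 + kq_tau0 * qs[i])), 1))
  dyn <- assess_lifetime_invariance(fits_dyn, qs)
  expect_equal(dyn$verdict, "dynamic")
  expect_lt(abs(dyn$kq_tau0 / kq_tau0 - 1), 0.10)

  expect_error(assess_lifetime_invariance(fits_inv, c(1e-5, 1e-4, 3e-4)),
               "zero-quencher")
})

test_that("reduced chi-square of the true model is centred on 1", {
  chi <- vapply(1:20, function(s)
    fit_multiexponential(single_exp_decay(300 + s, tau = 5), 1)$reduced_chi_square,
    0)
  expect_lt(abs(mean(chi) - 1), 0.1)
})
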