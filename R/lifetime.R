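#' Multi-exponential decay model
#'
#' Sum-of-exponentials intensity decay `I(t) = sum_i a_i exp(-t / tau_i)`,
#' with up to three components, an optional IRF colour shift and a constant
#' background. Components are stored sorted by ascending lifetime.
#'
#' @param amplitudes Non-negative amplitudes (arbitrary units, sum > 0).
#' @param lifetimes Lifetimes in ns (> 0), same length (1 to 3 components).
#' @param shift IRF colour shift in ns (default 0).
#' @param background Constant background, counts per channel (>= 0).
#' @return An object of class `decay_model`.
#' @export
decay_model <- function(amplitudes, lifetimes, shift = 0, background = 0) {
  amplitudes <- as.numeric(amplitudes)
  lifetimes <- as.numeric(lifetimes)
  n <- length(lifetimes)
  if (length(amplitudes) != n)
    stop("'amplitudes' and 'lifetimes' must have equal length", call. = FALSE)
  if (n < 1L || n > 3L)
    stop("1 to 3 exponential components supported", call. = FALSE)
  if (any(lifetimes <= 0) || any(!is.finite(lifetimes)))
    stop("lifetimes must be finite and > 0", call. = FALSE)
  if (any(amplitudes < 0) || sum(amplitudes) <= 0)
    stop("amplitudes must be >= 0 with positive sum", call. = FALSE)
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  ord <- order(lifetimes)
  structure(list(amplitudes = amplitudes[ord], lifetimes = lifetimes[ord],
                 n_exp = n, shift = shift, background = background),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model: %d component(s)>\n", x$n_exp))
  frac <- x$amplitudes / sum(x$amplitudes)
  for (i in seq_len(x$n_exp))
    cat(sprintf("  tau%d = %.4g ns  (amplitude fraction %.3f)\n",
                i, x$lifetimes[i], frac[i]))
  invisible(x)
}

#' Reconvolve a decay model with an instrument response function
#'
#' Discrete convolution of the multi-exponential model with the unit-area
#' IRF on a uniform channel grid, plus the model background. The IRF may be
#' `"delta"`, `list(type = "gaussian", center, fwhm)` (ns), or measured
#' counts (numeric vector or [decay_histogram()], normalised internally).
#' A nonzero model `shift` displaces the IRF by linear interpolation before
#' convolving.
#'
#' @param model A [decay_model()].
#' @param irf IRF specification (see above).
#' @param times Uniform channel-time grid in ns, starting at the first
#'   channel.
#' @return Expected counts per channel (same length as `times`).
#' @export
convolve_with_irf <- function(model, irf, times) {
  stopifnot(inherits(model, "decay_model"))
  n <- length(times)
  if (n < 3L || any(diff(times) <= 0))
    stop("'times' must be an increasing uniform grid", call. = FALSE)
  k <- .irf_kernel(irf, times)
  if (sum(k) <= 0) stop("IRF kernel is all zero", call. = FALSE)
  if (model$shift != 0) {
    k <- stats::approx(times, k, xout = times - model$shift,
                       yleft = 0, yright = 0)$y
    s <- sum(k)
    if (s <= 0) stop("IRF shifted off the grid", call. = FALSE)
    k <- k / s
  }
  t0 <- times - times[1]
  d <- colSums(model$amplitudes * exp(-outer(1 / model$lifetimes, t0)))
  if (identical(irf, "delta") && model$shift == 0) {
    out <- d           # exact convolution identity, no FFT round-off
  } else {
    full <- stats::convolve(d, rev(k), type = "open")
    out <- full[seq_len(n)]
    out[out < 0] <- 0  # FFT round-off
  }
  out + model$background
}

.default_irf <- function(hist, irf) {
  if (!is.null(irf)) return(irf)
  if (!is.null(hist$irf_counts)) hist$irf_counts else "delta"
}

#' Fit a multi-exponential reconvolution model to a TCSPC decay
#'
#' Weighted least squares with Poisson weights (variance = max(counts, 1),
#' standard TCSPC practice) on the reconvolved model, minimising chi-square
#' over amplitudes and lifetimes. Lifetimes are optimised on a log scale by
#' variable projection: for trial lifetimes the amplitudes (>= 0) solve a
#' small non-negative linear problem exactly, which keeps the search space
#' low-dimensional and robust to the close-lying lifetimes typical of
#' heterogeneous supramolecular emitters. A multi-start over lifetime
#' decades guards against local minima.
#'
#' @param hist A [decay_histogram()].
#' @param n_exp Number of exponential components (1 to 3).
#' @param irf IRF specification as in [convolve_with_irf()]; default: the
#'   histogram's own `irf_counts` when present, else a delta IRF.
#' @param fit_start First channel of the fit window; default the peak
#'   channel of the counts.
#' @param fit_end Last channel; default the final channel.
#' @param fit_background Also fit a constant background (default `FALSE`,
#'   background fixed at 0).
#' @param n_starts Number of multi-start initialisations (default 5),
#'   lifetimes log-spaced over \[channel width, 10 x record length\].
#' @return An object of class `decay_fit`: `model` (the fitted
#'   [decay_model()]), `reduced_chi_square`, `tau_amp` and `tau_int`
#'   (amplitude- and intensity-weighted average lifetimes), `stderr`
#'   (named vector for amplitudes and lifetimes), `covariance`, and the fit
#'   window. A warning is raised when two fitted lifetimes collapse within
#'   1% (over-parameterised model).
#' @export
fit_multiexponential <- function(hist, n_exp, irf = NULL,
                                 fit_start = NULL, fit_end = NULL,
                                 fit_background = FALSE, n_starts = 5L) {
  stopifnot(inherits(hist, "decay_histogram"))
  n_exp <- as.integer(n_exp)
  if (n_exp < 1L || n_exp > 3L) stop("n_exp must be 1, 2 or 3", call. = FALSE)
  y <- hist$counts
  times <- hist$channel_time
  nch <- length(y)
  if (sum(y) < 1000)
    stop("too few counts (< 1000) for a meaningful decay fit", call. = FALSE)
  if (2L * n_exp >= nch / 10)
    stop("model has too many parameters for this record length",
         call. = FALSE)
  irf <- .default_irf(hist, irf)

  if (is.null(fit_start)) fit_start <- which.max(y)
  if (is.null(fit_end)) fit_end <- nch
  win <- fit_start:fit_end
  w <- 1 / pmax(y[win], 1)

  ncol_lin <- n_exp + as.integer(fit_background)
  design <- function(log_tau) {
    taus <- exp(log_tau)
    X <- vapply(taus, function(tau) {
      m <- decay_model(1, tau)
      convolve_with_irf(m, irf, times)[win]
    }, numeric(length(win)))
    if (fit_background) X <- cbind(X, 1)
    X
  }

  # non-negative weighted LS by simple active-set elimination (<= 4 columns)
  nnls_w <- function(X, y, w) {
    active <- seq_len(ncol(X))
    repeat {
      coef <- rep(0, ncol(X))
      fit <- stats::lm.wfit(X[, active, drop = FALSE], y, w)
      coef[active] <- fit$coefficients
      coef[is.na(coef)] <- 0
      neg <- active[coef[active] < 0]
      if (!length(neg)) return(coef)
      active <- setdiff(active, neg[which.min(coef[neg])])
      if (!length(active)) return(rep(0, ncol(X)))
    }
  }

  obj <- function(log_tau) {
    if (any(!is.finite(log_tau))) return(1e30)
    X <- design(log_tau)
    coef <- nnls_w(X, y[win], w)
    sum(w * (y[win] - drop(X %*% coef))^2)
  }

  dt <- hist$channel_width
  record <- times[nch] - times[1]
  lo <- log(dt)
  hi <- log(10 * record)
  starts <- lapply(seq_len(n_starts), function(s) {
    span <- (hi - lo)
    centre <- lo + span * s / (n_starts + 1)
    if (n_exp == 1L) centre
    else centre + seq(-span / 6, span / 6, length.out = n_exp)
  })

  best <- NULL
  for (st in starts) {
    res <- if (n_exp == 1L) {
      o <- stats::optimize(function(l) obj(l), c(lo, hi), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(st, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value))
    stop("multi-exponential fit failed to converge after multi-start; ",
         "last chi-square was not finite", call. = FALSE)
  if (n_exp > 1L && best$convergence != 0L) {
    res <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 10000, reltol = 1e-12))
    if (res$value <= best$value) best <- res
    if (best$convergence != 0L)
      stop("multi-exponential fit did not converge (optimizer code ",
           best$convergence, "); chi-square = ", signif(best$value, 6),
           call. = FALSE)
  }

  log_tau <- sort(best$par)
  taus <- exp(log_tau)
  X <- design(log_tau)
  coef <- nnls_w(X, y[win], w)
  amps <- coef[seq_len(n_exp)]
  bg <- if (fit_background) max(coef[n_exp + 1L], 0) else 0

  if (n_exp > 1L) {
    rel <- diff(taus) / taus[-n_exp]
    if (any(rel < 0.01))
      warning("lifetime collapse: two fitted lifetimes agree within 1%; ",
              "the model is likely over-parameterised", call. = FALSE)
  }
  if (all(amps == 0))
    stop("fit degenerated to zero amplitude everywhere", call. = FALSE)
  amps_fit <- pmax(amps, 1e-12 * max(amps))  # keep decay_model valid
  model <- decay_model(amps_fit, taus, background = bg)

  npar <- 2L * n_exp + as.integer(fit_background)
  chi2_red <- best$value / (length(win) - npar)

  # covariance from the Gauss-Newton approximation at the optimum
  theta <- c(amps_fit, taus)
  pred_fun <- function(th) {
    m <- decay_model(pmax(th[seq_len(n_exp)], 0),
                     th[n_exp + seq_len(n_exp)], background = bg)
    convolve_with_irf(m, irf, times)[win]
  }
  J <- matrix(0, length(win), 2L * n_exp)
  base <- pred_fun(theta)
  for (j in seq_len(2L * n_exp)) {
    h <- max(abs(theta[j]), 1e-8) * 1e-6
    th <- theta; th[j] <- th[j] + h
    J[, j] <- (pred_fun(th) - base) / h
  }
  JtWJ <- crossprod(J * sqrt(w))
  cov <- tryCatch(solve(JtWJ), error = function(e)
    matrix(NA_real_, 2L * n_exp, 2L * n_exp))
  pn <- c(paste0("a", seq_len(n_exp)), paste0("tau", seq_len(n_exp)))
  dimnames(cov) <- list(pn, pn)
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- pn

  avg <- average_lifetimes(model)
  structure(list(model = model, reduced_chi_square = chi2_red,
                 tau_amp = avg$tau_amp, tau_int = avg$tau_int,
                 covariance = cov, stderr = se,
                 fit_window = c(fit_start, fit_end),
                 fitted = base, counts = y[win]),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("Reconvolution fit: %d exponential component(s), reduced chi^2 = %.3f\n",
              m$n_exp, x$reduced_chi_square))
  frac <- m$amplitudes / sum(m$amplitudes)
  for (i in seq_len(m$n_exp))
    cat(sprintf("  tau%d = %.4g ns (+/- %.2g), fraction %.3f\n",
                i, m$lifetimes[i], x$stderr[paste0("tau", i)], frac[i]))
  cat(sprintf("  <tau>_amp = %.4g ns, <tau>_int = %.4g ns\n",
              x$tau_amp, x$tau_int))
  invisible(x)
}

#' Amplitude- and intensity-weighted average lifetimes
#'
#' `tau_amp = sum(a_i tau_i) / sum(a_i)` and
#' `tau_int = sum(a_i tau_i^2) / sum(a_i tau_i)`. The intensity-weighted
#' average is never smaller than the amplitude-weighted one
#' (Cauchy-Schwarz), with equality only for a single lifetime.
#'
#' @param model A [decay_model()].
#' @return List with `tau_amp` and `tau_int` (ns).
#' @examples
#' average_lifetimes(decay_model(c(0.5, 0.5), c(2, 8)))  # 5.0 and 6.8 ns
#' @export
average_lifetimes <- function(model) {
  stopifnot(inherits(model, "decay_model"))
  a <- model$amplitudes
  tau <- model$lifetimes
  if (sum(a) <= 0) stop("amplitudes sum to zero", call. = FALSE)
  if (model$n_exp == 1L)     # both averages are tau itself, exactly
    return(list(tau_amp = tau, tau_int = tau))
  tau_amp <- sum(a * tau) / sum(a)
  tau_int <- sum(a * tau^2) / sum(a * tau)
  # Cauchy-Schwarz guarantees tau_int >= tau_amp; guard the <= 1 ulp
  # round-off violation possible when the lifetimes nearly coincide
  list(tau_amp = tau_amp, tau_int = max(tau_int, tau_amp))
}

#' Choose the number of exponential components
#'
#' Helper (not automatic policy): fits 1..`max_n` components and prefers
#' the richer model only when the nested F-test on the weighted residual
#' sums improves the fit at level `alpha`.
#'
#' @param hist A [decay_histogram()].
#' @param max_n Maximum components to consider (<= 3).
#' @param irf IRF specification (see [fit_multiexponential()]).
#' @param alpha F-test level (default 0.05).
#' @param ... Passed to [fit_multiexponential()].
#' @return List with `n_exp` (chosen order) and `fits` (all fits).
#' @export
select_n_exp <- function(hist, max_n = 3L, irf = NULL, alpha = 0.05, ...) {
  fits <- list()
  chosen <- 1L
  for (n in seq_len(max_n)) {
    fits[[n]] <- suppressWarnings(
      fit_multiexponential(hist, n, irf = irf, ...))
    if (n > 1L) {
      win_n <- diff(fits[[n]]$fit_window) + 1L
      rss1 <- fits[[n - 1L]]$reduced_chi_square * (win_n - 2 * (n - 1))
      rss2 <- fits[[n]]$reduced_chi_square * (win_n - 2 * n)
      df2 <- win_n - 2 * n
      Fstat <- ((rss1 - rss2) / 2) / (rss2 / df2)
      p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
      if (is.finite(p) && p < alpha) chosen <- n else break
    }
  }
  list(n_exp = chosen, fits = fits)
}

#' Lifetime invariance across quencher concentrations
#'
#' Static-vs-dynamic discrimination from time-resolved data: in purely
#' static quenching (ground-state complex formation) the decay of the
#' remaining free fluorophore is unchanged, so every lifetime and amplitude
#' fraction stays constant as quencher is added; in dynamic (collisional)
#' quenching the lifetime shortens as `tau0 / tau = 1 + k_q tau0 [Q]`.
#'
#' @param fits List of [fit_multiexponential()] results, one per quencher
#'   level, all with the same number of components.
#' @param guest_totals Quencher (guest) total concentrations, mol/L, same
#'   order; must include 0 (the reference).
#' @param k Reporting tolerance: the largest per-parameter deviation (in
#'   combined-sigma units) is compared against `k` (default 3) in the
#'   returned diagnostics.
#' @param alpha_invariance Level of the joint chi-square test on all
#'   parameter deviations from the zero-quencher fit (default 1e-3). A
#'   joint test is used for the verdict, rather than the per-parameter
#'   `k`-sigma screen, because the latter's familywise false-alarm rate
#'   grows with the number of lifetimes, fractions and quencher levels
#'   compared.
#' @param alpha_dynamic One-sided significance level for a positive
#'   Stern-Volmer slope of `tau0/tau` vs \[Q\] (default 1e-3).
#' @return An object of class `lifetime_invariance`: `verdict`
#'   (`"invariant"`, `"dynamic"` or `"inconclusive"`), `kq_tau0` (the
#'   fitted dynamic Stern-Volmer slope, 1/M), its stderr and p-value, the
#'   joint-test p-value `p_invariance`, and the per-parameter maximum
#'   deviation in combined-sigma units.
#' @export
assess_lifetime_invariance <- function(fits, guest_totals, k = 3,
                                       alpha_invariance = 1e-3,
                                       alpha_dynamic = 1e-3) {
  if (length(fits) != length(guest_totals) || length(fits) < 2L)
    stop("need matching fits and guest_totals for >= 2 quencher levels",
         call. = FALSE)
  iz <- which(guest_totals == 0)
  if (length(iz) != 1L)
    stop("need exactly one zero-quencher reference fit", call. = FALSE)
  n_exp <- vapply(fits, function(f) f$model$n_exp, 0L)
  if (length(unique(n_exp)) != 1L)
    stop("all fits must use the same number of components", call. = FALSE)
  ne <- n_exp[1]

  params <- function(f) {
    a <- f$model$amplitudes
    c(f$model$lifetimes, if (ne > 1L) (a / sum(a))[-ne])
  }
  par_se <- function(f) {
    se_tau <- f$stderr[paste0("tau", seq_len(ne))]
    if (ne == 1L) return(se_tau)
    # amplitude-fraction stderr by error propagation (ignoring covariance)
    a <- f$model$amplitudes; s <- sum(a)
    se_a <- f$stderr[paste0("a", seq_len(ne))]
    se_frac <- sqrt(((s - a)^2 * se_a^2 +
                       a^2 * (sum(se_a^2) - se_a^2)) / s^4)
    c(se_tau, se_frac[-ne])
  }

  p0 <- params(fits[[iz]]); s0 <- par_se(fits[[iz]])
  zmax <- 0
  for (i in setdiff(seq_along(fits), iz)) {
    z <- abs(params(fits[[i]]) - p0) / sqrt(par_se(fits[[i]])^2 + s0^2)
    zmax <- max(zmax, z[is.finite(z)])
  }

  # Cochran-Q heterogeneity per parameter across all levels (the reference
  # is one level among the others; comparing each level to the reference
  # instead would correlate the comparisons through the shared reference
  # noise and inflate the joint statistic)
  par_mat <- vapply(fits, params, numeric(length(p0)))
  se_mat <- vapply(fits, par_se, numeric(length(p0)))
  par_mat <- matrix(par_mat, nrow = length(p0))
  se_mat <- matrix(se_mat, nrow = length(p0))
  chi2 <- 0; df <- 0L
  for (p in seq_len(nrow(par_mat))) {
    ok <- is.finite(se_mat[p, ]) & se_mat[p, ] > 0
    if (sum(ok) < 2L) next
    w <- 1 / se_mat[p, ok]^2
    tbar <- sum(w * par_mat[p, ok]) / sum(w)
    chi2 <- chi2 + sum(w * (par_mat[p, ok] - tbar)^2)
    df <- df + sum(ok) - 1L
  }
  p_inv <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
           else NA_real_

  # dynamic Stern-Volmer test on the intensity-weighted average lifetime:
  # tau0/tau - 1 regressed through the origin on [Q], weighted by the
  # ratio variance propagated from the per-fit lifetime standard errors
  # (a z-test; robust even with only two nonzero quencher levels)
  tau <- vapply(fits, function(f) f$tau_int, 0)
  se_tau <- vapply(fits, function(f) {
    s <- f$stderr[paste0("tau", seq_len(ne))]
    if (ne == 1L) unname(s) else {
      # propagate through tau_int = sum(a t^2)/sum(a t), lifetimes only
      a <- f$model$amplitudes; tl <- f$model$lifetimes
      g <- (2 * a * tl * sum(a * tl) - a * sum(a * tl^2)) / sum(a * tl)^2
      sqrt(sum((g * s)^2))
    }
  }, 0)
  ratio <- tau[iz] / tau
  var_ratio <- ratio^2 * ((se_tau[iz] / tau[iz])^2 + (se_tau / tau)^2)
  q <- guest_totals
  keep <- seq_along(q)[-iz]
  slope <- NA_real_; slope_se <- NA_real_; p_dyn <- NA_real_
  ok <- keep[is.finite(var_ratio[keep]) & var_ratio[keep] > 0]
  if (length(ok) >= 1L) {
    w <- 1 / var_ratio[ok]
    slope <- sum(w * q[ok] * (ratio[ok] - 1)) / sum(w * q[ok]^2)
    slope_se <- 1 / sqrt(sum(w * q[ok]^2))
    p_dyn <- stats::pnorm(slope / slope_se, lower.tail = FALSE)
  }

  verdict <- if (is.finite(p_dyn) && p_dyn < alpha_dynamic && slope > 0)
    "dynamic"
  else if (is.finite(p_inv) && p_inv >= alpha_invariance) "invariant"
  else "inconclusive"

  structure(list(verdict = verdict, kq_tau0 = slope,
                 kq_tau0_stderr = slope_se, p_dynamic = p_dyn,
                 p_invariance = p_inv,
                 max_deviation_sigma = zmax, within_k = zmax <= k, k = k),
            class = "lifetime_invariance")
}

#' @export
print.lifetime_invariance <- function(x, ...) {
  cat(sprintf("Lifetime invariance assessment: %s\n", x$verdict))
  cat(sprintf("  max parameter deviation: %.2f sigma (reporting tolerance %g); joint p = %.3g\n",
              x$max_deviation_sigma, x$k, x$p_invariance))
  if (is.finite(x$kq_tau0))
    cat(sprintf("  dynamic SV slope (kq tau0): %.4g 1/M (p = %.3g)\n",
                x$kq_tau0, x$p_dynamic))
  invisible(x)
}
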