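#' Stern-Volmer fit of a quenching titration
#'
#' Fits F0/F = 1 + K \[Q\] by least squares on (guest concentration, F0/F).
#' For 1:1 static quenching with a non-emissive complex the slope is the
#' association constant (1/M). With `use_corrected = TRUE` the measured
#' intensities are first corrected for the excitation inner filter effect
#' ([correct_excitation_ife()]); comparing the corrected and uncorrected
#' slopes quantifies how much an absorbing quencher inflates the apparent
#' constant.
#'
#' @param series A [titration_series()].
#' @param use_corrected Correct intensities for the excitation IFE before
#'   fitting (requires `A_ex` or `spectra`).
#' @param spectra Optional per-point absorbance spectra for the correction.
#' @param geometry Geometry for the correction; defaults to the series'
#'   own.
#' @param fix_intercept Fix the intercept at 1 (default; the plot passes
#'   through F0/F = 1 by construction). With `FALSE` the intercept is
#'   fitted and its deviation from 1 is a systematic-error diagnostic.
#' @param refine_free_guest Iterate the fit with the free guest
#'   concentration from [solve_equilibrium_1to1()] on the x-axis instead of
#'   the total. Matters only when the bound guest is not negligible against
#'   the total (host concentration comparable to the lowest guest points).
#' @param max_points Use only the first `max_points` titrant points
#'   (explicit truncation; a message is logged). Default: all points.
#' @return An object of class `sv_fit` with elements `K` (slope, 1/M),
#'   `K_stderr`, `intercept`, `r_squared` (NA when the intensities carry no
#'   variance), `corrected`, `points_used`, `curvature_flag` (TRUE when a
#'   quadratic term improves the fit at the 0.05 level, the signature of
#'   uncorrected IFE data bending upward), `p_slope_positive` (one-sided
#'   p-value that the slope is > 0) and the plot-ready `data`.
#' @examples
#' sc <- simulation_scenario(K_true = 3000, host_total = 1e-5,
#'                           guest_grid = seq(0, 3e-4, length.out = 12),
#'                           eps_guest = 1000, noise_rel_F = 0)
#' ts <- simulate_fluorescence_titration(sc)
#' stern_volmer_fit(ts, use_corrected = TRUE)$K
#' stern_volmer_fit(ts, use_corrected = FALSE)$K  # inflated by the IFE
#' @export
stern_volmer_fit <- function(series, use_corrected = FALSE, spectra = NULL,
                             geometry = series$geometry,
                             fix_intercept = TRUE,
                             refine_free_guest = FALSE,
                             max_points = NULL) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  Fv <- if (use_corrected) {
    dA <- delta_absorbance(series, "ex", spectra)
    correct_excitation_ife(pts$F, dA, geometry)
  } else pts$F

  if (any(Fv <= 0))
    stop("non-positive fluorescence intensity; cannot form F0/F ratios",
         call. = FALSE)
  ref <- reference_index(series)
  F0 <- Fv[ref]
  titrant <- which(pts$guest_total > 0)
  if (!is.null(max_points) && length(titrant) > max_points) {
    message(sprintf("truncating Stern-Volmer fit to the first %d titrant points",
                    max_points))
    titrant <- titrant[seq_len(max_points)]
  }
  if (length(titrant) < 3L)
    stop("need at least 3 titrant points for a Stern-Volmer fit",
         call. = FALSE)

  q_tot <- pts$guest_total[titrant]
  ratio <- F0 / Fv[titrant]
  host <- pts$host_total[titrant]

  fit_once <- function(x) {
    if (fix_intercept) {
      fit <- stats::lm(I(ratio - 1) ~ 0 + x)
      slope_term <- "x"
      intercept <- 1
    } else {
      fit <- stats::lm(ratio ~ x)
      slope_term <- "x"
      intercept <- unname(stats::coef(fit)[1])
    }
    sm <- summary(fit)$coefficients
    list(fit = fit, K = unname(sm[slope_term, "Estimate"]),
         se = unname(sm[slope_term, "Std. Error"]),
         tval = unname(sm[slope_term, "t value"]),
         df = stats::df.residual(fit), intercept = intercept)
  }

  x <- q_tot
  res <- fit_once(x)
  if (refine_free_guest) {
    for (i in seq_len(50)) {
      K_prev <- res$K
      eq <- solve_equilibrium_1to1(max(res$K, 0), host, q_tot)
      x <- eq$free_guest
      res <- fit_once(x)
      if (abs(res$K - K_prev) <= 1e-10 * max(abs(res$K), 1e-30)) break
    }
  }

  y <- if (fix_intercept) ratio - 1 else ratio
  fitted_y <- stats::fitted(res$fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-20 * max(1, mean(y)^2)) NA_real_
        else 1 - sum(stats::residuals(res$fit)^2) / tss

  # upward curvature of uncorrected IFE data: nested-model F-test;
  # skipped when the linear fit is already exact to numerical noise
  curv <- FALSE
  resid_scale <- sqrt(mean(stats::residuals(res$fit)^2))
  if (length(x) >= 4L && resid_scale > 1e-8 * mean(abs(ratio))) {
    f_lin <- res$fit
    f_quad <- if (fix_intercept) stats::lm(I(ratio - 1) ~ 0 + x + I(x^2))
              else stats::lm(ratio ~ x + I(x^2))
    an <- stats::anova(f_lin, f_quad)
    pcurv <- an[["Pr(>F)"]][2]
    curv <- is.finite(pcurv) && pcurv < 0.05
  }

  p_pos <- stats::pt(res$tval, df = res$df, lower.tail = FALSE)

  structure(list(K = res$K, K_stderr = res$se, intercept = res$intercept,
                 r_squared = r2, corrected = use_corrected,
                 points_used = length(x), curvature_flag = curv,
                 p_slope_positive = p_pos,
                 fix_intercept = fix_intercept,
                 refine_free_guest = refine_free_guest,
                 data = data.frame(guest_total = q_tot, x_fit = x,
                                   ratio = ratio)),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (%s intensities)\n",
              if (x$corrected) "IFE-corrected" else "uncorrected"))
  cat(sprintf("  K = %.4g +/- %.2g 1/M  (n = %d, R^2 = %s)\n",
              x$K, x$K_stderr, x$points_used,
              if (is.na(x$r_squared)) "undefined (flat data)"
              else sprintf("%.4f", x$r_squared)))
  if (x$curvature_flag)
    cat("  warning: significant upward curvature (quadratic term, p < 0.05);\n",
        "  typical of uncorrected inner-filter attenuation\n")
  invisible(x)
}

#' Classify the strength of an association constant
#'
#' Policy mirror of the usual reading of spectrophotometric titration
#' results: constants that are tiny or statistically indistinguishable from
#' zero indicate only "statistical complexes" (random proximity); large,
#' significant constants indicate a stable complex.
#'
#' @param K Association constant, 1/M.
#' @param K_stderr Its standard error (1/M).
#' @param statistical_M Below this (default 1), or when K < 2 stderr, the
#'   association is classed `statistical`.
#' @param weak_M At or above this (default 100, and significant), the
#'   association is classed `stable`; in between, `weak`.
#' @return One of `"statistical"`, `"weak"`, `"stable"`.
#' @export
classify_association <- function(K, K_stderr,
                                 statistical_M = 1, weak_M = 100) {
  stopifnot(is.finite(K), is.finite(K_stderr))
  significant <- K >= 2 * K_stderr
  if (K < statistical_M || !significant) "statistical"
  else if (K >= weak_M) "stable"
  else "weak"
}

#' Global fit of a spectrophotometric (UV-Vis) titration
#'
#' Estimates the 1:1 association constant from absorbance data alone by
#' nonlinear least squares over K (and the complex absorptivity spectrum),
#' with predicted absorbance
#' `A(lambda, point) = eps_H(lambda)[H] + eps_G(lambda)[G] + eps_HG(lambda)[HG]`
#' and speciation from [solve_equilibrium_1to1()]. For fixed K the problem
#' is linear in eps_HG, which is profiled out (non-negative least squares
#' per wavelength); K is optimised on a log10 scale for conditioning, with
#' K >= 0 enforced by the parameterisation.
#'
#' @param series A [titration_series()] (>= 4 points).
#' @param spectra List of per-point absorbance [spectrum()] objects. When
#'   `NULL`, the single-wavelength `A_ex` column is used instead.
#' @param eps_host,eps_guest Known molar absorptivities of the pure
#'   components ([spectrum()] or scalar, 1/M/cm).
#' @param wl_window Optional `c(min, max)` nm window restricting the fitted
#'   wavelengths.
#' @param log10K_range Search range for log10(K); default `c(-3, 8)`.
#' @return An object of class `binding_fit`: `K`, `K_stderr`,
#'   `eps_complex` (fitted complex absorptivity), `residual_rms` (AU),
#'   `identifiable` (`FALSE` when the best-fit binding signal is below 3x
#'   the residual noise, i.e. the absorbance carries no binding
#'   information).
#' @export
global_absorbance_fit <- function(series, spectra = NULL, eps_host, eps_guest,
                                  wl_window = NULL,
                                  log10K_range = c(-3, 8)) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  if (nrow(pts) < 4L)
    stop("need at least 4 titration points for a global absorbance fit",
         call. = FALSE)

  if (!is.null(spectra)) {
    if (length(spectra) != nrow(pts))
      stop("need one spectrum per titration point", call. = FALSE)
    wl <- spectra[[1]]$wavelengths
    for (sp in spectra)
      if (!isTRUE(all.equal(sp$wavelengths, wl)))
        stop("all point spectra must share one wavelength grid", call. = FALSE)
    if (!is.null(wl_window)) {
      keep <- wl >= wl_window[1] & wl <= wl_window[2]
      if (!any(keep)) stop("empty wavelength window", call. = FALSE)
    } else keep <- rep(TRUE, length(wl))
    wl <- wl[keep]
    A <- do.call(rbind, lapply(spectra, function(sp) sp$values[keep]))
  } else {
    if (!"A_ex" %in% names(pts))
      stop("no spectra and no A_ex column: nothing to fit", call. = FALSE)
    wl <- series$lambda_ex
    A <- matrix(pts$A_ex, ncol = 1L)
  }
  eH <- .eps_at(eps_host, wl)
  eG <- .eps_at(eps_guest, wl)

  ht <- pts$host_total
  gt <- pts$guest_total

  rss_of <- function(K) {
    eq <- solve_equilibrium_1to1(K, ht, gt)
    R <- A - outer(eq$free_host, eH) - outer(eq$free_guest, eG)
    hg <- eq$complex
    denom <- sum(hg^2)
    eHG <- if (denom > 0) pmax(colSums(R * hg) / denom, 0) else rep(0, ncol(A))
    resid <- R - outer(hg, eHG)
    list(rss = sum(resid^2), eHG = eHG,
         pred = A - resid, complex = hg)
  }

  # coarse log10 K grid, then local refinement in the bracketing interval
  grid <- seq(log10K_range[1], log10K_range[2], length.out = 56)
  rss_grid <- vapply(grid, function(l) rss_of(10^l)$rss, 0)
  rss0 <- rss_of(0)$rss
  i <- which.min(rss_grid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(function(l) rss_of(10^l)$rss, c(lo, hi),
                         tol = 1e-10)
  if (rss0 < opt$objective) {
    K_hat <- 0
    best <- rss_of(0)
  } else {
    K_hat <- 10^opt$minimum
    best <- rss_of(K_hat)
  }
  if (!is.finite(best$rss))
    stop("global absorbance fit diverged; last K = ", K_hat, call. = FALSE)

  npar <- 1L + ncol(A)
  dof <- max(length(A) - npar, 1L)
  sigma2 <- best$rss / dof
  resid_rms <- sqrt(sigma2)

  # curvature of RSS(K) at the optimum -> large-sample stderr of K
  K_se <- NA_real_
  if (K_hat > 0) {
    h <- K_hat * 1e-4
    d2 <- (rss_of(K_hat + h)$rss - 2 * best$rss + rss_of(K_hat - h)$rss) / h^2
    if (is.finite(d2) && d2 > 0) K_se <- sqrt(2 * sigma2 / d2)
  }

  # binding signal: does the best fit differ from the no-association model?
  pred0 <- outer(ht, eH) + outer(gt, eG)
  signal <- max(abs(best$pred - pred0))
  identifiable <- signal > 3 * resid_rms + 1e-12 * max(abs(A), 1)

  eps_complex <- if (length(wl) > 1L) spectrum(wl, best$eHG, "absorbance")
                 else best$eHG
  structure(list(K = K_hat, K_stderr = K_se, eps_complex = eps_complex,
                 residual_rms = resid_rms, identifiable = identifiable,
                 n_wavelengths = length(wl), n_points = nrow(pts)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Global absorbance (1:1 mass-action) fit\n")
  cat(sprintf("  K = %.4g 1/M (stderr %s), residual rms %.3g AU, %d points x %d wavelengths\n",
              x$K, if (is.finite(x$K_stderr)) sprintf("%.2g", x$K_stderr) else "n/a",
              x$residual_rms, x$n_points, x$n_wavelengths))
  if (!x$identifiable)
    cat("  note: binding signal below 3x noise; K is not identifiable from",
        "these spectra\n")
  invisible(x)
}
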