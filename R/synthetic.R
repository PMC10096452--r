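#' Ground-truth scenario for synthetic titrations
#'
#' Describes a cell-by-cell titration of a fluorescent host with a quencher
#' (guest) whose 1:1 association constant, absorption coefficients and noise
#' levels are all known, so that downstream estimators can be validated by
#' parameter recovery. Molar absorption coefficients may be scalars (value
#' at the relevant wavelength) or [spectrum()] objects (per-wavelength,
#' interpreted as molar absorptivity in 1/M/cm).
#'
#' @param K_true True association constant, 1/M (>= 0).
#' @param host_total Constant total host concentration, mol/L (> 0).
#' @param guest_grid Vector of total guest concentrations, mol/L, containing
#'   exactly one zero (the reference point).
#' @param eps_host,eps_guest,eps_complex Molar absorption coefficients at
#'   the excitation wavelength (1/M/cm, >= 0), scalar or [spectrum()];
#'   `eps_complex` defaults to `eps_host + eps_guest` (no absorbance change
#'   on complexation).
#' @param eps_host_em,eps_guest_em Coefficients at the emission wavelength,
#'   used only when `emission_ife = TRUE`. Default 0.
#' @param complex_emissive_fraction Emissivity of the bound host relative to
#'   free host, in \[0, 1\]; 0 means a fully quenched (dark) complex.
#' @param F0 Fluorescence intensity of the zero-guest reference solution
#'   (arbitrary units).
#' @param noise_rel_F Relative s.d. of the multiplicative Gaussian noise on
#'   F (default 0.01, typical fluorimeter repeatability).
#' @param noise_rel_A Relative s.d. of the Gaussian noise on absorbances
#'   (default 0.002, typical photometric precision).
#' @param include_host_complexation_ife If `TRUE`, the simulated
#'   excitation-filter attenuation also includes the absorbance change of
#'   the host upon complexation; by default only the guest's own absorption
#'   at the excitation wavelength attenuates (the usual situation with
#'   strongly absorbing quenchers).
#' @param emission_ife If `TRUE`, also attenuate by the absorbance at the
#'   emission wavelength over the effective emission path. Default off.
#' @param lambda_ex,lambda_em Wavelengths in nm.
#' @param geometry A [geometry()].
#' @param seed Integer seed; simulations are bit-reproducible given the
#'   scenario.
#' @return An object of class `simulation_scenario`.
#' @seealso [simulate_fluorescence_titration()],
#'   [simulate_absorbance_titration()]
#' @export
simulation_scenario <- function(K_true, host_total, guest_grid,
                                eps_host = 0, eps_guest = 0,
                                eps_complex = NULL,
                                eps_host_em = 0, eps_guest_em = 0,
                                complex_emissive_fraction = 0,
                                F0 = 1000,
                                noise_rel_F = 0.01, noise_rel_A = 0.002,
                                include_host_complexation_ife = FALSE,
                                emission_ife = FALSE,
                                lambda_ex = 300, lambda_em = 375,
                                geometry = quenchkit::geometry(),
                                seed = 1L) {
  stopifnot(is.finite(K_true), K_true >= 0,
            is.finite(host_total), host_total > 0,
            inherits(geometry, "geometry"))
  guest_grid <- sort(as.numeric(guest_grid))
  if (sum(guest_grid == 0) != 1L || any(guest_grid < 0))
    stop("'guest_grid' must be >= 0 and contain exactly one zero",
         call. = FALSE)
  if (complex_emissive_fraction < 0 || complex_emissive_fraction > 1)
    stop("'complex_emissive_fraction' must lie in [0, 1]", call. = FALSE)
  chk_eps <- function(e, what) {
    if (inherits(e, "spectrum")) return(e)
    e <- as.numeric(e)
    if (length(e) != 1L || !is.finite(e) || e < 0)
      stop(sprintf("'%s' must be a non-negative scalar or a spectrum", what),
           call. = FALSE)
    e
  }
  eps_host <- chk_eps(eps_host, "eps_host")
  eps_guest <- chk_eps(eps_guest, "eps_guest")
  if (is.null(eps_complex)) {
    eps_complex <- if (inherits(eps_host, "spectrum") ||
                       inherits(eps_guest, "spectrum")) NULL
                   else eps_host + eps_guest
  }
  if (!is.null(eps_complex)) eps_complex <- chk_eps(eps_complex, "eps_complex")
  structure(list(K_true = K_true, host_total = host_total,
                 guest_grid = guest_grid,
                 eps_host = eps_host, eps_guest = eps_guest,
                 eps_complex = eps_complex,
                 eps_host_em = eps_host_em, eps_guest_em = eps_guest_em,
                 complex_emissive_fraction = complex_emissive_fraction,
                 F0 = F0, noise_rel_F = noise_rel_F,
                 noise_rel_A = noise_rel_A,
                 include_host_complexation_ife = include_host_complexation_ife,
                 emission_ife = emission_ife,
                 lambda_ex = lambda_ex, lambda_em = lambda_em,
                 geometry = geometry, seed = as.integer(seed)),
            class = "simulation_scenario")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

.eps_at <- function(eps, wavelength) {
  if (inherits(eps, "spectrum")) spectrum_at(eps, wavelength) else eps
}

.scenario_speciation <- function(scenario) {
  solve_equilibrium_1to1(scenario$K_true, scenario$host_total,
                         scenario$guest_grid)
}

#' Simulate a UV-Vis absorbance titration
#'
#' For each point of the guest grid, computes the 1:1 speciation at the true
#' association constant and builds the absorbance by Beer-Lambert additivity
#' over free host, free guest and complex (1 cm path), then adds Gaussian
#' noise. When the scenario's absorption coefficients are [spectrum()]
#' objects, a per-point absorbance [spectrum()] over their common grid is
#' returned as well.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list with elements `series` (a [titration_series()] whose
#'   `A_ex` column holds the noisy absorbance at the excitation wavelength;
#'   the `F` column is filled with the noiseless fluorescence so the series
#'   validates, but fluorescence analysis should use
#'   [simulate_fluorescence_titration()]), `spectra` (list of per-point
#'   absorbance spectra, or `NULL` for scalar coefficients) and `truth`
#'   (the speciation table used).
#' @export
simulate_absorbance_titration <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  spc <- .scenario_speciation(sc)

  spectral <- inherits(sc$eps_host, "spectrum") ||
    inherits(sc$eps_guest, "spectrum") ||
    inherits(sc$eps_complex, "spectrum")
  spectra <- NULL

  .with_seed(sc$seed, {
    if (spectral) {
      grids <- lapply(Filter(function(e) inherits(e, "spectrum"),
                             list(sc$eps_host, sc$eps_guest, sc$eps_complex)),
                      `[[`, "wavelengths")
      wl <- sort(unique(unlist(grids)))
      wl <- wl[wl >= max(vapply(grids, min, 0)) &
                 wl <= min(vapply(grids, max, 0))]
      eH <- .eps_at(sc$eps_host, wl)
      eG <- .eps_at(sc$eps_guest, wl)
      eC <- if (is.null(sc$eps_complex)) eH + eG else .eps_at(sc$eps_complex, wl)
      spectra <- lapply(seq_len(nrow(spc)), function(i) {
        a <- eH * spc$free_host[i] + eG * spc$free_guest[i] +
          eC * spc$complex[i]
        a <- a + stats::rnorm(length(a), 0, sc$noise_rel_A * pmax(a, 0))
        spectrum(wl, pmax(a, -0.0099), "absorbance")
      })
      A_ex <- vapply(spectra, spectrum_at, 0, wavelength = sc$lambda_ex)
    } else {
      eC <- if (is.null(sc$eps_complex)) sc$eps_host + sc$eps_guest
            else sc$eps_complex
      A_true <- sc$eps_host * spc$free_host + sc$eps_guest * spc$free_guest +
        eC * spc$complex
      A_ex <- A_true + stats::rnorm(length(A_true), 0,
                                    sc$noise_rel_A * A_true)
    }
    pts <- data.frame(host_total = sc$host_total,
                      guest_total = sc$guest_grid,
                      F = sc$F0 * (spc$free_host +
                        sc$complex_emissive_fraction * spc$complex) /
                        sc$host_total,
                      A_ex = A_ex)
    series <- titration_series(pts, lambda_ex = sc$lambda_ex,
                               lambda_em = sc$lambda_em,
                               geometry = sc$geometry,
                               label = "synthetic absorbance titration")
    list(series = series, spectra = spectra, truth = spc)
  })
}

#' Simulate an IFE-attenuated fluorescence quenching titration
#'
#' The true emitted intensity is proportional to the free host plus the
#' emissive fraction of the complex. The simulator then APPLIES the
#' excitation inner-filter attenuation that the Eq.-style correction is
#' meant to remove: the observed intensity is
#' `F_true * 10^(-dA_ex * d_ex)`, where `dA_ex = eps_guest * guest_total`
#' (1 cm basis) is the absorbance added by the guest at the excitation
#' wavelength and `d_ex` the effective excitation path in cm. Multiplicative
#' Gaussian noise is applied to F, and the `A_ex` column is populated (with
#' its own noise) so the correction can be driven from the series alone.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [titration_series()] with attributes `truth` (speciation) and
#'   `F_true` (noiseless unattenuated intensities).
#' @export
simulate_fluorescence_titration <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  spc <- .scenario_speciation(sc)
  eH <- .eps_at(sc$eps_host, sc$lambda_ex)
  eG <- .eps_at(sc$eps_guest, sc$lambda_ex)
  eC <- if (is.null(sc$eps_complex)) eH + eG
        else .eps_at(sc$eps_complex, sc$lambda_ex)

  F_true <- sc$F0 * (spc$free_host + sc$complex_emissive_fraction *
                       spc$complex) / sc$host_total

  dA_ex <- eG * sc$guest_grid
  if (sc$include_host_complexation_ife)
    dA_ex <- dA_ex + (eC - eH - eG) * spc$complex
  atten <- 10^(-dA_ex * sc$geometry$eff_excitation_path_cm /
                 sc$geometry$cell_path_cm)

  A_em <- NULL
  if (sc$emission_ife) {
    dA_em <- sc$eps_guest_em * sc$guest_grid
    atten <- atten * 10^(-dA_em * sc$geometry$eff_emission_path_cm /
                           sc$geometry$cell_path_cm)
    A_em_true <- sc$eps_host_em * sc$host_total +
      sc$eps_guest_em * sc$guest_grid
  }

  A_ex_true <- eH * sc$host_total + dA_ex

  .with_seed(sc$seed, {
    Fobs <- F_true * atten
    Fobs <- Fobs * (1 + stats::rnorm(length(Fobs), 0, sc$noise_rel_F))
    A_ex <- A_ex_true + stats::rnorm(length(A_ex_true),
                                     0, sc$noise_rel_A * A_ex_true)
    pts <- data.frame(host_total = sc$host_total,
                      guest_total = sc$guest_grid,
                      F = pmax(Fobs, 0), A_ex = A_ex)
    if (sc$emission_ife)
      pts$A_em <- A_em_true + stats::rnorm(length(A_em_true),
                                           0, sc$noise_rel_A * A_em_true)
    series <- titration_series(pts, lambda_ex = sc$lambda_ex,
                               lambda_em = sc$lambda_em,
                               geometry = sc$geometry,
                               label = "synthetic fluorescence titration")
    attr(series, "truth") <- spc
    attr(series, "F_true") <- F_true
    series
  })
}

#' Ground-truth scenario for synthetic TCSPC decays
#'
#' @param amplitudes,lifetimes Multi-exponential decay model: amplitudes
#'   (>= 0, arbitrary units) and lifetimes (ns, > 0), up to three
#'   components.
#' @param irf `"delta"`, `list(type = "gaussian", center, fwhm)` (ns), or a
#'   numeric vector / [decay_histogram()] of measured IRF counts on the same
#'   grid.
#' @param peak_counts Target maximum expected counts (typical TCSPC stop
#'   criterion, e.g. 1e4).
#' @param channels Number of channels.
#' @param channel_width Channel width in ns.
#' @param background Constant background, counts per channel.
#' @param seed Integer seed for the Poisson draw.
#' @return An object of class `decay_scenario`.
#' @export
decay_scenario <- function(amplitudes, lifetimes, irf = "delta",
                           peak_counts = 1e4, channels = 1024L,
                           channel_width = 0.05, background = 0,
                           seed = 1L) {
  model <- decay_model(amplitudes, lifetimes)
  stopifnot(peak_counts > 0, channels >= 16L, channel_width > 0,
            background >= 0)
  structure(list(model = model, irf = irf, peak_counts = peak_counts,
                 channels = as.integer(channels),
                 channel_width = channel_width, background = background,
                 seed = as.integer(seed)),
            class = "decay_scenario")
}

.irf_kernel <- function(irf, times) {
  n <- length(times)
  if (identical(irf, "delta")) {
    k <- numeric(n); k[1] <- 1
    return(k)
  }
  if (is.list(irf) && identical(irf$type, "gaussian")) {
    sigma <- irf$fwhm / (2 * sqrt(2 * log(2)))
    k <- stats::dnorm(times, mean = irf$center, sd = sigma)
    if (sum(k) <= 0) stop("gaussian IRF has no support on the grid",
                          call. = FALSE)
    return(k / sum(k))
  }
  k <- if (inherits(irf, "decay_histogram")) irf$counts else as.numeric(irf)
  if (length(k) != n) stop("measured IRF must match the channel grid",
                           call. = FALSE)
  if (any(k < 0) || sum(k) <= 0)
    stop("IRF counts must be non-negative with positive sum", call. = FALSE)
  k / sum(k)
}

#' Expected (noise-free) counts of a decay scenario
#'
#' The multi-exponential model reconvolved with the scenario IRF, scaled so
#' its maximum equals `peak_counts`, plus the background. This is the
#' Poisson mean used by [simulate_decay()].
#'
#' @param scenario A [decay_scenario()].
#' @return Numeric vector of expected counts per channel, with the channel
#'   time grid as attribute `channel_time`.
#' @export
decay_expected_counts <- function(scenario) {
  stopifnot(inherits(scenario, "decay_scenario"))
  times <- (seq_len(scenario$channels) - 1L) * scenario$channel_width
  irf <- .irf_kernel(scenario$irf, times)
  shape <- convolve_with_irf(scenario$model, irf, times)
  expected <- shape / max(shape) * scenario$peak_counts + scenario$background
  attr(expected, "channel_time") <- times
  expected
}

#' Simulate a TCSPC decay histogram
#'
#' Draws independent Poisson counts around the expected reconvolved decay
#' ([decay_expected_counts()]). For non-delta IRFs the (noise-free, integer
#' rounded) IRF profile is attached so reconvolution fits can use it.
#'
#' @param scenario A [decay_scenario()].
#' @return A [decay_histogram()].
#' @export
simulate_decay <- function(scenario) {
  expected <- decay_expected_counts(scenario)
  times <- attr(expected, "channel_time")
  counts <- .with_seed(scenario$seed,
                       stats::rpois(length(expected), expected))
  irf_counts <- NULL
  if (!identical(scenario$irf, "delta")) {
    k <- .irf_kernel(scenario$irf, times)
    irf_counts <- round(k / max(k) * scenario$peak_counts)
  }
  decay_histogram(times, counts, irf_counts)
}
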