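#' Absorbance change along a titration
#'
#' Per-point change in absorbance dA = A(point) - A(reference) at the
#' excitation or emission wavelength, on a 1 cm basis. The reference is the
#' zero-guest point, so the reference maps to exactly 0. When the series has
#' no `A_ex`/`A_em` column, per-point absorbance spectra may be supplied and
#' the absorbance at the wavelength is obtained by linear interpolation.
#'
#' @param series A [titration_series()].
#' @param wavelength `"ex"` (excitation, default) or `"em"` (emission).
#' @param spectra Optional list of per-point absorbance [spectrum()]
#'   objects, one per titration point in series order.
#' @return Numeric vector of dA values (AU, 1 cm basis), one per point.
#' @export
delta_absorbance <- function(series, wavelength = c("ex", "em"),
                             spectra = NULL) {
  stopifnot(inherits(series, "titration_series"))
  wavelength <- match.arg(wavelength)
  col <- if (wavelength == "ex") "A_ex" else "A_em"
  lam <- if (wavelength == "ex") series$lambda_ex else series$lambda_em
  if (col %in% names(series$points)) {
    A <- series$points[[col]]
  } else if (!is.null(spectra)) {
    if (length(spectra) != nrow(series$points))
      stop("need one spectrum per titration point", call. = FALSE)
    if (!is.finite(lam))
      stop("series does not record the wavelength needed to read spectra",
           call. = FALSE)
    A <- vapply(spectra, spectrum_at, 0, wavelength = lam)
  } else {
    stop(sprintf(
      paste("no '%s' absorbance available: supply the %s absorbance column",
            "or per-point spectra (e.g. from a UV-Vis titration)"),
      col, wavelength), call. = FALSE)
  }
  A - A[reference_index(series)]
}

#' Excitation inner-filter correction of a fluorescence intensity
#'
#' Removes the attenuation of the excitation beam caused by the absorbance
#' added on titration: `F_corr = F * 10^(dA * d_ex)`, where `dA` is the
#' absorbance change at the excitation wavelength (AU, 1 cm basis) and
#' `d_ex` the effective excitation path in cm. With the default geometry
#' (emission collected from the centre of a 1 cm cell, `d_ex = 0.5`) this is
#' exactly `F_corr = 10^(dA/2) * F`.
#'
#' @param F Measured fluorescence intensity (>= 0). Vectorised.
#' @param delta_A_ex Absorbance change(s) at the excitation wavelength (AU
#'   per 1 cm). Negative values (titrant bleaching the absorbance) are
#'   allowed and yield factors < 1, with a warning.
#' @param geometry A [geometry()].
#' @return Corrected intensity, same length as `F`.
#' @examples
#' correct_excitation_ife(100, 0.2)            # 100 * 10^0.1 = 125.89
#' correct_excitation_ife(100, 0.2, geometry(eff_excitation_path_cm = 1))
#' @export
correct_excitation_ife <- function(F, delta_A_ex, geometry = quenchkit::geometry()) {
  stopifnot(inherits(geometry, "geometry"))
  if (any(!is.finite(F)) || any(F < 0))
    stop("'F' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(delta_A_ex)))
    stop("'delta_A_ex' must be finite", call. = FALSE)
  if (any(delta_A_ex < 0))
    warning("negative delta-A: correction factors < 1 (titrant bleaches the absorbance)")
  F * 10^(delta_A_ex * geometry$eff_excitation_path_cm / geometry$cell_path_cm)
}

#' Emission inner-filter correction
#'
#' Symmetric factor `10^(dA_em * d_em)` for absorption of the emitted light
#' by the titrant. Off by default in the series-level pipeline; most
#' quenching studies (and this package's focus) deal with the excitation
#' side.
#'
#' @inheritParams correct_excitation_ife
#' @param delta_A_em Absorbance change(s) at the emission wavelength (AU per
#'   1 cm).
#' @return Corrected intensity.
#' @export
correct_emission_ife <- function(F, delta_A_em, geometry = quenchkit::geometry()) {
  stopifnot(inherits(geometry, "geometry"))
  if (any(!is.finite(F)) || any(F < 0))
    stop("'F' must be finite and >= 0", call. = FALSE)
  F * 10^(delta_A_em * geometry$eff_emission_path_cm / geometry$cell_path_cm)
}

#' Apply the inner-filter correction to a whole titration series
#'
#' Adds an `F_corr` column holding the excitation-corrected (and optionally
#' emission-corrected) intensities.
#'
#' @param series A [titration_series()].
#' @param spectra Optional per-point absorbance spectra (see
#'   [delta_absorbance()]).
#' @param emission Also apply the emission-side factor (requires `A_em` or
#'   spectra). Default `FALSE`.
#' @param geometry Geometry to use; defaults to the series' own.
#' @return The series with `points$F_corr` added.
#' @export
apply_ife_correction <- function(series, spectra = NULL, emission = FALSE,
                                 geometry = series$geometry) {
  dA_ex <- delta_absorbance(series, "ex", spectra)
  Fc <- correct_excitation_ife(series$points$F, dA_ex, geometry)
  if (emission) {
    dA_em <- delta_absorbance(series, "em", spectra)
    Fc <- correct_emission_ife(Fc, dA_em, geometry)
  }
  series$points$F_corr <- Fc
  series
}

#' Screen a titration for inner-filter-effect risk
#'
#' First gate of the sequential quenching diagnosis: how much absorbance at
#' the excitation (and, if available, emission) wavelength does the titrant
#' add, and is a correction warranted, or is the attenuation so large that
#' the experiment should be redesigned (different excitation wavelength or
#' shorter path)?
#'
#' @param series A [titration_series()].
#' @param spectra Optional per-point absorbance spectra.
#' @param negligible_AU Below this max dA_ex the IFE is negligible
#'   (default 0.01 AU, a 1.2% attenuation at 0.5 cm effective path).
#' @param redesign_AU Above this max dA_ex (default 1.0 AU, correction
#'   factor > ~3 at 0.5 cm) redesign is suggested rather than correction.
#' @param geometry Geometry for the per-point correction factors.
#' @return An object of class `ife_assessment`: max dA at both wavelengths,
#'   a verdict among `negligible` / `correct_required` /
#'   `redesign_suggested`, per-point correction factors, and an
#'   emission-side warning flag.
#' @export
screen_inner_filter <- function(series, spectra = NULL,
                                negligible_AU = 0.01, redesign_AU = 1.0,
                                geometry = series$geometry) {
  dA_ex <- delta_absorbance(series, "ex", spectra)
  max_ex <- max(dA_ex)
  verdict <- if (max_ex < negligible_AU) "negligible"
             else if (max_ex > redesign_AU) "redesign_suggested"
             else "correct_required"

  max_em <- NA_real_
  emission_warning <- FALSE
  em_available <- "A_em" %in% names(series$points) ||
    (!is.null(spectra) && is.finite(series$lambda_em))
  if (em_available) {
    dA_em <- delta_absorbance(series, "em", spectra)
    max_em <- max(dA_em)
    emission_warning <- max_em > negligible_AU
  }

  factors <- 10^(dA_ex * geometry$eff_excitation_path_cm /
                   geometry$cell_path_cm)
  structure(list(max_delta_A_ex = max_ex, max_delta_A_em = max_em,
                 verdict = verdict, per_point_factors = factors,
                 emission_warning = emission_warning,
                 thresholds = c(negligible_AU = negligible_AU,
                                redesign_AU = redesign_AU)),
            class = "ife_assessment")
}

#' @export
print.ife_assessment <- function(x, ...) {
  cat("Inner-filter-effect screen\n")
  cat(sprintf("  max dA(ex): %.4g AU -> verdict: %s\n",
              x$max_delta_A_ex, x$verdict))
  if (is.finite(x$max_delta_A_em))
    cat(sprintf("  max dA(em): %.4g AU%s\n", x$max_delta_A_em,
                if (x$emission_warning)
                  "  [warning: emission-side IFE above negligible threshold]"
                else ""))
  else cat("  emission side: not assessed (no A_em data)\n")
  cat(sprintf("  correction factors: 1 to %.4g\n",
              max(x$per_point_factors)))
  if (x$verdict == "redesign_suggested")
    cat("  recommendation: consider a different excitation wavelength or a",
        "shorter-path cell;\n  the correction factor exceeds ~3 and",
        "corrected intensities will be noise-amplified.\n")
  invisible(x)
}
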