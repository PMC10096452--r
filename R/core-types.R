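#' Absorption or emission spectrum
#'
#' A spectrum is a wavelength grid (nm, strictly increasing) paired with
#' absorbance (AU, normalised to 1 cm path) or emission intensity values
#' (arbitrary units).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values Numeric vector of the same length; absorbance in AU per
#'   1 cm path, or emission intensity in arbitrary units.
#' @param kind Either `"absorbance"` or `"emission"`.
#'
#' @return An object of class `spectrum`: a list with elements
#'   `wavelengths`, `values` and `kind`.
#'
#' @details A small negative absorbance baseline (down to -0.01 AU) is
#'   tolerated, as is common after blank subtraction; anything more negative
#'   is rejected.
#'
#' @examples
#' sp <- spectrum(c(280, 300, 320), c(0.10, 0.25, 0.05), "absorbance")
#' spectrum_at(sp, 310)
#' @export
spectrum <- function(wavelengths, values, kind = c("absorbance", "emission")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("'wavelengths' and 'values' must have equal length", call. = FALSE)
  if (length(wavelengths) < 1L)
    stop("spectrum must contain at least one point", call. = FALSE)
  if (anyNA(wavelengths) || anyNA(values) || any(!is.finite(values)))
    stop("spectrum contains non-finite entries", call. = FALSE)
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  if (kind == "absorbance" && any(values < -0.01))
    stop("absorbance values below -0.01 AU are not allowed", call. = FALSE)
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "spectrum")
}

#' Evaluate a spectrum at a wavelength
#'
#' Linear interpolation between the bracketing grid points; extrapolation
#' outside the grid is an error.
#'
#' @param sp A [spectrum()].
#' @param wavelength Wavelength in nm (scalar or vector).
#' @return Interpolated value(s).
#' @export
spectrum_at <- function(sp, wavelength) {
  stopifnot(inherits(sp, "spectrum"))
  rng <- range(sp$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf("wavelength outside spectrum range [%g, %g] nm",
                 rng[1], rng[2]), call. = FALSE)
  if (length(sp$wavelengths) == 1L) return(rep(sp$values, length(wavelength)))
  stats::approx(sp$wavelengths, sp$values, xout = wavelength)$y
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm>\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Optical geometry of the fluorescence measurement
#'
#' Captures the cell path length and the effective path lengths travelled by
#' the excitation beam before, and the emission beam after, the observed
#' emitting volume. With the defaults (1 cm cell, emission sampled from the
#' cell centre, so 0.5 cm effective paths on both sides) the excitation
#' inner-filter correction factor is exactly 10^(dA/2).
#'
#' @param cell_path_cm Cell optical path length in cm (> 0).
#' @param eff_excitation_path_cm Effective excitation path in cm (>= 0, <=
#'   `cell_path_cm`). Default 0.5.
#' @param eff_emission_path_cm Effective emission path in cm, used only when
#'   emission-side correction is requested. Default 0.5.
#' @return An object of class `geometry`.
#' @examples
#' geometry()                       # 1 cm cell, centre-of-cell observation
#' geometry(eff_excitation_path_cm = 1.0)  # front-face-like worst case
#' @export
geometry <- function(cell_path_cm = 1.0,
                     eff_excitation_path_cm = 0.5,
                     eff_emission_path_cm = 0.5) {
  if (!is.finite(cell_path_cm) || cell_path_cm <= 0)
    stop("'cell_path_cm' must be > 0", call. = FALSE)
  for (p in c(eff_excitation_path_cm, eff_emission_path_cm)) {
    if (!is.finite(p) || p < 0)
      stop("effective path lengths must be >= 0", call. = FALSE)
    if (p > cell_path_cm + 1e-12)
      stop("effective path lengths cannot exceed 'cell_path_cm'",
           call. = FALSE)
  }
  structure(list(cell_path_cm = cell_path_cm,
                 eff_excitation_path_cm = eff_excitation_path_cm,
                 eff_emission_path_cm = eff_emission_path_cm),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf(
    "<geometry: cell %g cm, eff. excitation path %g cm, eff. emission path %g cm>\n",
    x$cell_path_cm, x$eff_excitation_path_cm, x$eff_emission_path_cm))
  invisible(x)
}

#' TCSPC decay histogram
#'
#' Counts per channel from a time-correlated single-photon-counting
#' measurement, on a uniform time grid, with an optional instrument response
#' function (IRF) histogram measured on the same grid.
#'
#' @param channel_time Numeric vector of channel times in ns, uniformly
#'   spaced.
#' @param counts Non-negative integer counts per channel.
#' @param irf_counts Optional non-negative integer IRF counts, same length.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(channel_time, counts, irf_counts = NULL) {
  channel_time <- as.numeric(channel_time)
  n <- length(channel_time)
  if (n < 3L) stop("decay histogram needs at least 3 channels", call. = FALSE)
  dt <- diff(channel_time)
  if (any(dt <= 0) ||
      (max(dt) - min(dt)) > 1e-6 * abs(mean(dt)))
    stop("channel times must be uniformly spaced (1e-6 relative)",
         call. = FALSE)
  check_counts <- function(x, what) {
    x <- as.numeric(x)
    if (length(x) != n)
      stop(sprintf("'%s' must match the channel grid length", what),
           call. = FALSE)
    if (anyNA(x) || any(x < 0))
      stop(sprintf("'%s' must be non-negative", what), call. = FALSE)
    if (any(abs(x - round(x)) > 1e-9))
      stop(sprintf("'%s' must be integral counts", what), call. = FALSE)
    round(x)
  }
  counts <- check_counts(counts, "counts")
  if (!is.null(irf_counts)) irf_counts <- check_counts(irf_counts, "irf_counts")
  structure(list(channel_time = channel_time, counts = counts,
                 irf_counts = irf_counts,
                 channel_width = mean(dt)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "<decay_histogram: %d channels x %.4g ns, %s counts, IRF %s>\n",
    length(x$counts), x$channel_width,
    format(sum(x$counts), big.mark = ","),
    if (is.null(x$irf_counts)) "absent" else "present"))
  invisible(x)
}
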