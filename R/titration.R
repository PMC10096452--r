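#' Fluorescence/absorbance titration series
#'
#' An ordered set of titration points at increasing total guest (titrant)
#' concentration, all in mol/L, with the measured fluorescence intensity and
#' optional absorbances at the excitation and emission wavelengths
#' (normalised to 1 cm path). Exactly one point must have zero guest: it is
#' the reference defining F0 and A0.
#'
#' @param points A data.frame with columns `host_total`, `guest_total`, `F`
#'   (all required) and optionally `A_ex`, `A_em`. Concentrations in mol/L,
#'   absorbances in AU per 1 cm, `F` in arbitrary units (>= 0).
#' @param lambda_ex,lambda_em Excitation and emission wavelengths in nm.
#' @param geometry A [geometry()].
#' @param mode `"cell_by_cell"` (each point an independently prepared
#'   solution at constant host concentration) or `"cumulative_addition"`.
#' @param label Free-text provenance (e.g. whether `F` is a band maximum or
#'   an integrated band).
#'
#' @return An object of class `titration_series`. Points are stored sorted
#'   by ascending `guest_total`; a message is emitted if sorting changed the
#'   input order.
#' @examples
#' pts <- data.frame(host_total = 1e-5,
#'                   guest_total = c(0, 5e-5, 1e-4),
#'                   F = c(1000, 900, 820),
#'                   A_ex = c(0.20, 0.25, 0.30))
#' ts <- titration_series(pts, lambda_ex = 300, lambda_em = 375)
#' ts
#' @export
titration_series <- function(points, lambda_ex, lambda_em,
                             geometry = quenchkit::geometry(),
                             mode = c("cell_by_cell", "cumulative_addition"),
                             label = "") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(points), inherits(geometry, "geometry"))
  required <- c("host_total", "guest_total", "F")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in intersect(c(required, "A_ex", "A_em"), names(points)))
    points[[col]] <- as.numeric(points[[col]])

  bad <- which(points$host_total < 0 | points$guest_total < 0)
  if (length(bad))
    stop("negative concentration at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(points$F < 0 | !is.finite(points$F))
  if (length(bad))
    stop("fluorescence intensity must be finite and >= 0; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (col in intersect(c("A_ex", "A_em"), names(points))) {
    bad <- which(!is.finite(points[[col]]))
    if (length(bad))
      stop(sprintf("non-finite %s at row(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }

  n_ref <- sum(points$guest_total == 0)
  if (n_ref != 1L)
    stop(sprintf(
      "need exactly one zero-guest reference point (found %d)", n_ref),
      call. = FALSE)

  ord <- order(points$guest_total)
  if (is.unsorted(points$guest_total)) {
    message("titration points reordered to ascending guest_total")
    points <- points[ord, , drop = FALSE]
    rownames(points) <- NULL
  }

  if (mode == "cell_by_cell" && nrow(points) > 1L) {
    h <- points$host_total
    spread <- (max(h) - min(h)) / max(max(abs(h)), .Machine$double.xmin)
    if (spread > 1e-9)
      stop("cell_by_cell mode requires constant host_total across points",
           call. = FALSE)
  }

  structure(list(points = points, lambda_ex = lambda_ex,
                 lambda_em = lambda_em, geometry = geometry,
                 mode = mode, label = label),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  p <- x$points
  cat(sprintf(
    "<titration_series: %d points, host %.3g M, guest 0-%.3g M, lex %g nm, lem %g nm, %s>\n",
    nrow(p), p$host_total[1], max(p$guest_total), x$lambda_ex, x$lambda_em,
    x$mode))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Index of the zero-guest reference point
#' @param series A [titration_series()].
#' @return Integer row index into `series$points`.
#' @export
reference_index <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  which(series$points$guest_total == 0)
}

.detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"),
                   function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0L))
    stop("could not detect delimiter (comma, tab or semicolon) in: ", path,
         call. = FALSE)
  names(counts)[which.max(counts)]
}

.unit_factor <- function(unit) {
  switch(unit,
         "M" = 1, "mol/L" = 1,
         "mM" = 1e-3,
         "uM" = 1e-6, "µM" = 1e-6, "μM" = 1e-6,
         stop("unknown concentration unit: ", unit, call. = FALSE))
}

#' Read a titration table from delimited text
#'
#' Reads a delimited text file (comma, tab or semicolon; auto-detected) with
#' a header row into a [titration_series()]. Column names and concentration
#' units are declared through `schema`; concentrations are converted to
#' mol/L on read and absorbances are taken as AU per 1 cm path.
#'
#' @param path Path to the file.
#' @param schema Named list mapping the canonical column names
#'   (`host_total`, `guest_total`, `F`, optionally `A_ex`, `A_em`) to the
#'   column names used in the file, plus an optional `units` entry
#'   (`"M"`, `"mM"` or `"uM"`; default `"M"`) applying to both
#'   concentration columns.
#' @param geometry A [geometry()].
#' @param lambda_ex,lambda_em Wavelengths (nm) recorded on the series.
#' @param mode,label Passed to [titration_series()].
#' @return A [titration_series()].
#' @export
read_titration_series <- function(path, schema = list(), geometry = quenchkit::geometry(),
                                  lambda_ex = NA_real_, lambda_em = NA_real_,
                                  mode = "cell_by_cell", label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                           stringsAsFactors = FALSE, check.names = FALSE)
  units <- schema$units %||% "M"
  schema$units <- NULL
  canonical <- c("host_total", "guest_total", "F", "A_ex", "A_em")
  colmap <- stats::setNames(as.list(canonical), canonical)
  colmap[names(schema)] <- schema

  pts <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in canonical) {
    src <- colmap[[col]]
    if (src %in% names(raw)) {
      pts[[col]] <- as.numeric(raw[[src]])
    } else if (col %in% c("host_total", "guest_total", "F")) {
      stop(sprintf("required column '%s' (file column '%s') not found in %s",
                   col, src, path), call. = FALSE)
    }
  }
  fac <- .unit_factor(units)
  pts$host_total <- pts$host_total * fac
  pts$guest_total <- pts$guest_total * fac
  titration_series(pts, lambda_ex = lambda_ex, lambda_em = lambda_em,
                   geometry = geometry, mode = mode, label = label)
}

#' Write a titration series to delimited text
#'
#' Writes the points table as comma-separated text with concentrations in
#' mol/L, the canonical column names, and absorbances per 1 cm, so that
#' [read_titration_series()] with the default schema round-trips the series.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_titration_series <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  utils::write.table(series$points, path, sep = ",", dec = ".",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TCSPC decay histogram from delimited text
#'
#' Expects two or three numeric columns: channel time (ns), decay counts
#' and, optionally, IRF counts on the same grid. A header row is accepted.
#'
#' @param path Path to the file.
#' @return A [decay_histogram()]. When no third column is present the IRF is
#'   absent and downstream fits must use an analytic (delta or Gaussian)
#'   IRF.
#' @export
read_decay_histogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_delimiter(path)
  first <- utils::read.table(path, sep = sep, nrows = 1L,
                             stringsAsFactors = FALSE)
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  tab <- utils::read.table(path, header = has_header, sep = sep, dec = ".")
  if (!ncol(tab) %in% c(2L, 3L))
    stop("decay file must have 2 or 3 columns (time, counts[, irf]): ", path,
         call. = FALSE)
  decay_histogram(channel_time = tab[[1]], counts = tab[[2]],
                  irf_counts = if (ncol(tab) == 3L) tab[[3]])
}

#' Write a decay histogram to delimited text
#' @param hist A [decay_histogram()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_decay_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  tab <- data.frame(time_ns = hist$channel_time, counts = hist$counts)
  if (!is.null(hist$irf_counts)) tab$irf_counts <- hist$irf_counts
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
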