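#' Spectra
#'
#' A spectrum couples a wavelength grid with one intensity series of the
#' same length (arbitrary units). Intensities must be finite.
#'
#' @param wavelength a [make_wavelength_grid()] object or strictly
#'   increasing numeric vector (nm).
#' @param intensity numeric vector of intensities (a.u.), same length as the
#'   grid.
#' @param comments optional character vector of comment lines carried as
#'   metadata (written as `#` lines by [write_spectrum()]).
#' @return A `spectrum` object: list with `wavelength`, `intensity`,
#'   `comments`.
#' @export
spectrum <- function(wavelength, intensity, comments = character()) {
  grid <- as_wavelength_grid(wavelength)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(grid$values))
    stop_invalid("intensity length (", length(intensity),
                 ") does not match the grid (", length(grid$values), ")")
  if (!all(is.finite(intensity)))
    stop_invalid("intensities must be finite")
  structure(list(wavelength = grid$values, intensity = intensity,
                 comments = as.character(comments)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.6g to %.6g nm, intensity [%.4g, %.4g] a.u.\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Drop short wavelengths from a spectrum
#'
#' Retains only wavelengths strictly greater than `lambda_min`. This mirrors
#' the usual preprocessing of fluorescence measurements where the excitation
#' region carries no emission signal (e.g. dropping everything at or below
#' 400 nm).
#'
#' @param x a [spectrum()].
#' @param lambda_min cut-off (nm); points with wavelength `<= lambda_min`
#'   are removed.
#' @return The truncated [spectrum()].
#' @export
cut_wavelengths <- function(x, lambda_min) {
  stopifnot(inherits(x, "spectrum"))
  keep <- x$wavelength > lambda_min
  if (!any(keep))
    stop_degenerate("no wavelengths remain above ", lambda_min, " nm")
  spectrum(x$wavelength[keep], x$intensity[keep], x$comments)
}

#' Pointwise average of spectra
#'
#' Averages several measurements of the same source on a shared grid, the
#' standard way to beat down zero-mean noise (residual noise scales as
#' 1/sqrt(n)). Used, for instance, to build a reference spectrum from
#' repeated unit-concentration measurements.
#'
#' @param spectra a list of [spectrum()] objects on one common grid.
#' @return A [spectrum()] holding the pointwise mean.
#' @export
average_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 1 ||
      !all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop_invalid("'spectra' must be a non-empty list of spectrum objects")
  w <- spectra[[1]]$wavelength
  for (s in spectra[-1]) {
    if (length(s$wavelength) != length(w) || any(s$wavelength != w))
      stop_invalid("all spectra must share one wavelength grid")
  }
  m <- vapply(spectra, function(s) s$intensity, numeric(length(w)))
  spectrum(w, rowMeans(as.matrix(m)))
}

#' Read and write two-column spectrum files
#'
#' The on-disk format is plain UTF-8 text: any number of comment lines
#' starting with `#`, then one `wavelength<TAB>intensity` pair per line with
#' `.` as decimal separator. Values round-trip to 12 significant digits and
#' comment lines are preserved as metadata.
#'
#' @param path file path.
#' @param x a [spectrum()].
#' @return `read_spectrum()` returns a [spectrum()]; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("spectrum file not found: ", path),
                        class = c("pinncal_not_found", "error")))
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) < 2)
    stop_invalid("spectrum file has fewer than 2 data rows: ", path)
  fields <- strsplit(trimws(lines[data_idx]), "[\t ,;]+")
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad))
    stop_invalid("malformed row at line ", data_idx[bad[1]], " of ", path)
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f), numeric(2)))
  nonnum <- which(!is.finite(vals[1, ]) | !is.finite(vals[2, ]))
  if (length(nonnum))
    stop_invalid("non-numeric value at line ", data_idx[nonnum[1]], " of ", path)
  comments <- sub("^\\s*#\\s?", "", lines[is_comment])
  spectrum(vals[1, ], vals[2, ], comments)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(x$comments))
    writeLines(paste0("# ", x$comments), con)
  writeLines(sprintf("%.15g\t%.15g", x$wavelength, x$intensity), con)
  invisible(path)
}
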