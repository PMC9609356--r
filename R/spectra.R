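#' Construct a fluorescence emission spectrum
#'
#' An `emission_spectrum` holds one emission scan on a strictly increasing,
#' uniformly spaced wavelength grid, together with acquisition metadata.
#' Negative intensities are permitted only as a transient state after
#' background subtraction and are carried with a `negative` flag rather than
#' clipped, so that downstream intensity ratios are not biased.
#'
#' @param wavelengths Numeric vector of wavelengths in nm; strictly
#'   increasing with constant step (tolerance 1e-9 nm).
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `wavelengths`; all values must be finite.
#' @param excitation_nm Excitation wavelength in nm.
#' @param temperature_C Acquisition temperature in degrees Celsius.
#' @param n_scans_averaged Number of raw scans averaged into this spectrum.
#' @param negative Logical flag marking the presence of negative intensities
#'   (set automatically by [subtract_background()]).
#'
#' @return An object of class `emission_spectrum`.
#' @seealso [average_scans()], [subtract_background()],
#'   [smooth_moving_average()], [peak_emission()]
#' @export
#' @examples
#' wl <- 310:500
#' sp <- emission_spectrum(wl, exp(-((wl - 328) / 25)^2 / 2), excitation_nm = 295)
#' peak_emission(sp)
emission_spectrum <- function(wavelengths, intensities, excitation_nm = NA_real_,
                              temperature_C = NA_real_, n_scans_averaged = 1L,
                              negative = FALSE) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) == 0L)
    stop_memfluor("empty wavelength grid", "empty_input")
  if (length(intensities) != length(wavelengths))
    stop_memfluor("intensities and wavelengths differ in length", "grid_mismatch")
  if (!all(is.finite(wavelengths)) || !all(is.finite(intensities)))
    stop_memfluor("non-finite wavelength or intensity values", "invalid_data")
  if (length(wavelengths) > 1L) {
    steps <- diff(wavelengths)
    if (any(steps <= 0))
      stop_memfluor("wavelengths must be strictly increasing", "invalid_grid")
    if (max(steps) - min(steps) > 1e-9)
      stop_memfluor("wavelength grid must be uniform (tolerance 1e-9 nm)",
                    "invalid_grid")
  }
  if (!negative && any(intensities < 0))
    negative <- TRUE
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         excitation_nm = excitation_nm, temperature_C = temperature_C,
         n_scans_averaged = as.integer(n_scans_averaged),
         negative = isTRUE(negative)),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("Emission spectrum: %d points, %.6g-%.6g nm", length(x$wavelengths),
              rng[1], rng[2]))
  if (is.finite(x$excitation_nm)) cat(sprintf(", ex %.6g nm", x$excitation_nm))
  cat(sprintf(", %d scan(s) averaged", x$n_scans_averaged))
  if (x$negative) cat(" [negative intensities flagged]")
  cat("\n")
  invisible(x)
}

#' @export
plot.emission_spectrum <- function(x, ..., xlab = "Wavelength (nm)",
                                   ylab = "Intensity (a.u.)", type = "l") {
  plot(x$wavelengths, x$intensities, xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(abs(a$wavelengths - b$wavelengths) <= 1e-9)
}

#' Average repeated emission scans
#'
#' Pointwise arithmetic mean of repeated scans acquired on the same
#' wavelength grid at the same excitation wavelength. Replicate scan counts
#' accumulate in `n_scans_averaged`.
#'
#' @param spectra Non-empty list of [emission_spectrum] objects with
#'   identical wavelength grids and excitation wavelengths.
#' @return An [emission_spectrum] with the mean intensities.
#' @export
#' @examples
#' wl <- 310:320
#' s1 <- emission_spectrum(wl, rep(2, 11), 295)
#' s2 <- emission_spectrum(wl, rep(4, 11), 295)
#' average_scans(list(s1, s2))$intensities[1]  # 3
average_scans <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L)
    stop_memfluor("average_scans needs a non-empty list of spectra", "empty_input")
  ref <- spectra[[1L]]
  for (sp in spectra) {
    if (!inherits(sp, "emission_spectrum"))
      stop_memfluor("all elements must be emission_spectrum objects", "invalid_data")
    if (!same_grid(ref, sp))
      stop_memfluor("wavelength grids do not match", "grid_mismatch")
    if (!identical(is.na(ref$excitation_nm), is.na(sp$excitation_nm)) ||
        (!is.na(ref$excitation_nm) && ref$excitation_nm != sp$excitation_nm))
      stop_memfluor("excitation wavelengths do not match", "grid_mismatch")
  }
  mat <- vapply(spectra, function(s) s$intensities, numeric(length(ref$wavelengths)))
  mat <- matrix(mat, nrow = length(ref$wavelengths))
  emission_spectrum(ref$wavelengths, rowMeans(mat),
                    excitation_nm = ref$excitation_nm,
                    temperature_C = ref$temperature_C,
                    n_scans_averaged = sum(vapply(spectra, function(s)
                      s$n_scans_averaged, integer(1L))))
}

#' Subtract a blank (background) spectrum
#'
#' Pointwise subtraction of a buffer/blank scan from a sample scan. Negative
#' results are retained and flagged, never clipped, because clipping would
#' bias downstream relative-intensity ratios.
#'
#' @param sample,blank [emission_spectrum] objects on identical grids.
#' @return An [emission_spectrum]; its `negative` flag is `TRUE` when any
#'   corrected intensity is negative.
#' @export
subtract_background <- function(sample, blank) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(blank, "emission_spectrum"))
  if (!same_grid(sample, blank))
    stop_memfluor("sample and blank wavelength grids do not match", "grid_mismatch")
  corrected <- sample$intensities - blank$intensities
  emission_spectrum(sample$wavelengths, corrected,
                    excitation_nm = sample$excitation_nm,
                    temperature_C = sample$temperature_C,
                    n_scans_averaged = sample$n_scans_averaged,
                    negative = any(corrected < 0))
}

#' Moving-average smoothing of a spectrum
#'
#' Centred moving mean with an odd window (default 5 points, the usual
#' spectrofluorimeter setting). Near the edges the window shrinks
#' symmetrically: at point `i` the half-width is reduced to the largest
#' radius that keeps the window inside the grid, so edge points are averaged
#' over fewer, still symmetric, neighbours.
#'
#' @param spectrum An [emission_spectrum].
#' @param window Odd positive integer window width, at most the spectrum
#'   length.
#' @return The smoothed [emission_spectrum].
#' @export
smooth_moving_average <- function(spectrum, window = 5L) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (!is_number(window) || window < 1 || window %% 2 != 1)
    stop_memfluor("window must be an odd positive integer", "invalid_parameter")
  n <- length(spectrum$intensities)
  if (window > n)
    stop_memfluor("window exceeds spectrum length", "invalid_parameter")
  h <- (as.integer(window) - 1L) %/% 2L
  y <- spectrum$intensities
  out <- vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)
    mean(y[(i - r):(i + r)])
  }, numeric(1L))
  emission_spectrum(spectrum$wavelengths, out,
                    excitation_nm = spectrum$excitation_nm,
                    temperature_C = spectrum$temperature_C,
                    n_scans_averaged = spectrum$n_scans_averaged,
                    negative = spectrum$negative)
}

#' Locate the emission maximum
#'
#' Returns the wavelength and intensity of the maximum within an optional
#' search range. Ties are broken toward the lower wavelength. A spectrum
#' with all-equal intensities is degenerate: a warning is raised and the
#' lowest wavelength in range is returned.
#'
#' @param spectrum An [emission_spectrum].
#' @param search_range Optional numeric length-2 interval (nm) restricting
#'   the search; must intersect the grid.
#' @return Named list with `lambda_max` (nm) and `I_max` (a.u.).
#' @export
peak_emission <- function(spectrum, search_range = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelengths
  y <- spectrum$intensities
  if (!is.null(search_range)) {
    stopifnot(is.numeric(search_range), length(search_range) == 2L)
    keep <- wl >= min(search_range) & wl <= max(search_range)
    if (!any(keep))
      stop_memfluor("search_range does not intersect the wavelength grid",
                    "invalid_parameter")
    wl <- wl[keep]; y <- y[keep]
  }
  if (length(unique(y)) == 1L)
    warn_memfluor("all intensities equal: degenerate peak, returning lowest wavelength",
                  "degenerate_peak")
  i <- which.max(y)  # which.max takes the first maximum: low-wavelength tie-break
  list(lambda_max = wl[i], I_max = y[i])
}
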