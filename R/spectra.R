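# Fluorescence emission-spectrum descriptors: emission maximum, spectral
# shift, intensity ratios.

#' Emission spectrum container
#'
#' @param wavelength strictly increasing wavelengths, nm.
#' @param intensity non-negative intensities, arbitrary units.
#' @param meta optional named list (excitation nm, urea M, construction, ...).
#' @return an object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, intensity, meta = list()) {
  .check_finite(wavelength, "wavelength"); .check_finite(intensity, "intensity")
  if (length(wavelength) != length(intensity))
    stop("length mismatch", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(wavelength = wavelength, intensity = intensity, meta = meta),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("Emission spectrum: %d points, %.0f-%.0f nm\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Wavelength of maximal emission
#'
#' Smooths the spectrum with a moving average, takes the discrete maximum and
#' refines it by quadratic interpolation through the three surrounding points.
#' A maximum sitting at the edge of the scanned range is unreliable (the true
#' band maximum may lie outside); the result then carries an `edge` attribute
#' set to `TRUE`.
#'
#' @param spectrum an [emission_spectrum()] with >= 20 points spanning
#'   >= 60 nm.
#' @param smooth_window moving-average window in nm (default 5).
#' @return the emission maximum in nm, with logical attribute `edge`.
#' @export
emission_maximum <- function(spectrum, smooth_window = 5) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  if (length(wl) < 20 || diff(range(wl)) < 60)
    stop("need >= 20 points spanning >= 60 nm", call. = FALSE)
  dl <- stats::median(diff(wl))
  k <- max(1L, round(smooth_window / dl))
  ys <- .movavg(spectrum$intensity, k)
  j <- which.max(ys)
  edge <- j <= 1L || j >= length(ys)
  if (edge) {
    out <- wl[j]
  } else {
    y1 <- ys[j - 1]; y2 <- ys[j]; y3 <- ys[j + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
    out <- wl[j] + max(-1, min(1, off)) * dl
    # flat spectra have no usable maximum either
    if (max(ys) - min(ys) < 1e-9 * max(abs(ys), 1)) edge <- TRUE
  }
  structure(out, edge = edge)
}

#' Spectral shift between two emission spectra
#'
#' Signed difference of emission maxima; positive values mean `b` is
#' red-shifted relative to `a` (Trp residues more solvent-exposed), negative
#' values a blue shift.
#'
#' @param a,b [emission_spectrum()] objects.
#' @param ... passed to [emission_maximum()].
#' @return shift in nm with attribute `edge` (TRUE if either maximum was
#'   edge-flagged).
#' @export
spectral_shift <- function(a, b, ...) {
  ma <- emission_maximum(a, ...)
  mb <- emission_maximum(b, ...)
  structure(as.numeric(mb) - as.numeric(ma),
            edge = isTRUE(attr(ma, "edge")) || isTRUE(attr(mb, "edge")))
}

#' Intensity ratio at two wavelengths
#'
#' Linear-interpolated intensity at `num_nm` divided by that at `den_nm`. The
#' default pair (355, 337) is the classic tryptophan exposure index: the
#' ratio grows as the emission band moves from the buried-Trp (~330 nm) to
#' the exposed-Trp (~355 nm) position.
#'
#' @param spectrum an [emission_spectrum()].
#' @param num_nm,den_nm numerator and denominator wavelengths, nm; must lie
#'   inside the scanned range.
#' @return dimensionless ratio.
#' @export
intensity_ratio <- function(spectrum, num_nm = 355, den_nm = 337) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  if (num_nm < min(wl) || num_nm > max(wl) ||
      den_nm < min(wl) || den_nm > max(wl))
    stop("requested wavelength outside the scanned range", call. = FALSE)
  num <- stats::approx(wl, spectrum$intensity, num_nm)$y
  den <- stats::approx(wl, spectrum$intensity, den_nm)$y
  if (den <= 0) stop("denominator intensity is not positive", call. = FALSE)
  num / den
}
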