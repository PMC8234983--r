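# CSV readers/writers for the four data types. Files are plain
# comma-separated text with a header; the x unit of curve files must be
# declared explicitly (M or C) — it is never guessed.

.read_csv2col <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!stats::complete.cases(d[cols]) |
                 !vapply(seq_len(nrow(d)),
                         function(i) all(is.finite(unlist(d[i, cols]))), TRUE))
  if (length(bad))
    stop("non-finite value(s) in ", path, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  d
}

#' Read a denaturation curve from CSV
#'
#' Expects columns `x` and `signal` (renameable via `x_col`/`y_col`). The
#' unit of x must be given: `"M"` loads a chemical curve, `"C"` a thermal one
#' with temperatures converted to Kelvin internally.
#'
#' @param path CSV file path.
#' @param unit `"M"` (denaturant molarity) or `"C"` (temperature in Celsius).
#' @param x_col,y_col column names (defaults `"x"`, `"signal"`).
#' @param meta optional metadata list merged into the curve.
#' @return a [denaturation_curve()]; its metadata records the source path.
#' @export
read_curve <- function(path, unit, x_col = "x", y_col = "signal",
                       meta = list()) {
  if (missing(unit) || !unit %in% c("M", "C"))
    stop("unit must be 'M' (chemical) or 'C' (thermal); it is never guessed",
         call. = FALSE)
  d <- .read_csv2col(path, c(x_col, y_col))
  x <- d[[x_col]]; y <- d[[y_col]]
  if (unit == "C") x <- celsius_to_kelvin(x)
  meta$path <- path
  denaturation_curve(x, y, mode = if (unit == "M") "chemical" else "thermal",
                     meta = meta)
}

#' Write a denaturation curve to CSV
#'
#' Thermal curves are written with temperature in Celsius (column `x`,
#' unit noted in the `unit` column of the header comment-free layout:
#' the unit is carried by the caller's knowledge and the read-side `unit`
#' argument).
#'
#' @param curve a [denaturation_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "denaturation_curve"))
  x <- curve$x
  if (.curve_mode(curve) == "thermal") x <- kelvin_to_celsius(x)
  utils::write.csv(data.frame(x = x, signal = curve$y), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a DSC thermogram from CSV
#'
#' Expects columns `temperature_C` and `cp`.
#'
#' @param path CSV file path.
#' @param ... passed to [dsc_thermogram()] (flags, scan rate, ...).
#' @return a [dsc_thermogram()].
#' @export
read_dsc <- function(path, ...) {
  d <- .read_csv2col(path, c("temperature_C", "cp"))
  dsc_thermogram(d$temperature_C, d$cp, ...)
}

#' @rdname read_dsc
#' @param thermogram a [dsc_thermogram()] to write.
#' @export
write_dsc <- function(thermogram, path) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  utils::write.csv(data.frame(temperature_C = kelvin_to_celsius(thermogram$T),
                              cp = thermogram$cp),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an emission spectrum from CSV
#'
#' Expects columns `wavelength_nm` and `intensity`.
#'
#' @param path CSV file path.
#' @return an [emission_spectrum()].
#' @export
read_spectrum <- function(path) {
  d <- .read_csv2col(path, c("wavelength_nm", "intensity"))
  emission_spectrum(d$wavelength_nm, d$intensity, meta = list(path = path))
}

#' @rdname read_spectrum
#' @param spectrum an [emission_spectrum()] to write.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a c(s) distribution from CSV
#'
#' Expects columns `s_svedberg` and `signal`.
#'
#' @param path CSV file path.
#' @return a [cs_distribution()].
#' @export
read_cs <- function(path) {
  d <- .read_csv2col(path, c("s_svedberg", "signal"))
  cs_distribution(d$s_svedberg, d$signal, meta = list(path = path))
}

#' @rdname read_cs
#' @param dist a [cs_distribution()] to write.
#' @export
write_cs <- function(dist, path) {
  stopifnot(inherits(dist, "cs_distribution"))
  utils::write.csv(data.frame(s_svedberg = dist$s, signal = dist$signal),
                   path, row.names = FALSE)
  invisible(path)
}
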