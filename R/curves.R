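#' Denaturation curve container
#'
#' An ordered set of (x, signal) observations from an equilibrium unfolding
#' experiment. For `mode = "chemical"` x is denaturant concentration (M); for
#' `mode = "thermal"` x is absolute temperature (K; use
#' [celsius_to_kelvin()] when constructing from instrument output).
#'
#' @param x strictly increasing numeric vector (M or K), length >= 12.
#' @param y fluorescence intensity (arbitrary units), same length as `x`.
#' @param mode `"chemical"` or `"thermal"`.
#' @param meta optional named list of metadata (construction label, subunit
#'   concentration in uM, excitation/emission wavelengths in nm, generator
#'   truth for synthetic curves, ...).
#' @return an object of class `denaturation_curve`: a data frame with columns
#'   `x`, `y` and attributes `mode` and `meta`.
#' @export
denaturation_curve <- function(x, y, mode = c("chemical", "thermal"),
                               meta = list()) {
  mode <- match.arg(mode)
  .check_finite(x, "x"); .check_finite(y, "y")
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 12)
    stop("a denaturation curve needs at least 12 points (got ", length(x), ")",
         call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  structure(data.frame(x = x, y = y),
            mode = mode, meta = meta,
            class = c("denaturation_curve", "data.frame"))
}

#' @export
print.denaturation_curve <- function(x, ...) {
  md <- attr(x, "mode")
  rng <- range(x$x)
  if (md == "thermal")
    cat(sprintf("Thermal denaturation curve: %d points, %.1f-%.1f C\n",
                nrow(x), kelvin_to_celsius(rng[1]), kelvin_to_celsius(rng[2])))
  else
    cat(sprintf("Chemical denaturation curve: %d points, %.2f-%.2f M\n",
                nrow(x), rng[1], rng[2]))
  meta <- attr(x, "meta")
  keep <- setdiff(names(meta), "truth")
  if (length(keep))
    cat("  meta:", paste(keep, unlist(meta[keep]), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

.curve_mode <- function(curve) attr(curve, "mode")

.as_curve_list <- function(curves) {
  if (inherits(curves, "denaturation_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, TRUE,
                                     "denaturation_curve")))
    stop("expected a denaturation_curve or a list of them", call. = FALSE)
  modes <- vapply(curves, .curve_mode, "")
  if (length(unique(modes)) != 1L)
    stop("curves of mixed mode (chemical + thermal) cannot be fitted together",
         call. = FALSE)
  curves
}
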