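# AUC interpretive arithmetic downstream of c(s): s20,w standardization,
# frictional ratio, and peak-fraction integration of c(s) distributions.
# Solvent physical properties (density, viscosity, vbar) are user inputs;
# computing them from buffer composition is out of scope.

#' Solvent conditions for sedimentation standardization
#'
#' @param density solvent density, g mL^-1.
#' @param viscosity solvent viscosity, mPa s (cP).
#' @param temperature solvent temperature, K.
#' @return an object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(density, viscosity, temperature = 293.15) {
  if (density <= 0 || viscosity <= 0 || temperature <= 0)
    stop("solvent properties must be > 0", call. = FALSE)
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature), class = "solvent_conditions")
}

#' Water at 20 or 25 degrees C
#'
#' Reference solvent conditions (density in g/mL, viscosity in mPa s).
#'
#' @param temperature_C 20 or 25.
#' @return a [solvent_conditions()] object.
#' @export
water_conditions <- function(temperature_C = 20) {
  if (temperature_C == 20)
    solvent_conditions(.RHO_W20, .ETA_W20, 293.15)
  else if (temperature_C == 25)
    solvent_conditions(0.99705, 0.8902, 298.15)
  else stop("defaults provided only for water at 20 or 25 C", call. = FALSE)
}

#' Standardize a sedimentation coefficient to water at 20 C
#'
#' \deqn{s_{20,w} = s_{obs} \frac{\eta_{solvent}}{\eta_{w,20}}
#'  \frac{1 - \bar v \rho_{w,20}}{1 - \bar v \rho_{solvent}}}
#'
#' @param s_obs observed sedimentation coefficient, S.
#' @param solvent a [solvent_conditions()] object for the experimental buffer.
#' @param vbar protein partial specific volume, mL g^-1 (default 0.73, a
#'   typical protein value).
#' @return standardized sedimentation coefficient s20,w, S.
#' @export
s20w <- function(s_obs, solvent, vbar = 0.73) {
  stopifnot(inherits(solvent, "solvent_conditions"))
  .check_finite(s_obs, "s_obs")
  b_solv <- 1 - vbar * solvent$density
  b_w20 <- 1 - vbar * .RHO_W20
  if (b_solv <= 0 || b_w20 <= 0)
    stop("non-positive buoyancy term (1 - vbar*rho); check vbar and density",
         call. = FALSE)
  s_obs * (solvent$viscosity / .ETA_W20) * (b_w20 / b_solv)
}

#' Frictional ratio f/f0 from s20,w and molar mass
#'
#' Ratio of the Stokes radius implied by the sedimentation coefficient to the
#' radius of the equivalent anhydrous sphere:
#' \deqn{R_s = \frac{M (1 - \bar v \rho_{w,20})}{N_A 6 \pi \eta_{w,20} s_{20,w}},
#'  \quad R_0 = \left(\frac{3 M \bar v}{4 \pi N_A}\right)^{1/3}.}
#' Compact globular proteins give ~1.2-1.3; extended or unfolded chains give
#' substantially larger values. A value below 1 (beyond a 0.02 tolerance) is
#' non-physical and flagged with a warning, but still returned.
#'
#' @param s20w standardized sedimentation coefficient, S.
#' @param M molar mass of the sedimenting species, g mol^-1.
#' @param vbar partial specific volume, mL g^-1 (default 0.73).
#' @return dimensionless frictional ratio.
#' @export
frictional_ratio <- function(s20w, M, vbar = 0.73) {
  if (s20w <= 0 || M <= 0 || vbar <= 0)
    stop("s20w, M and vbar must be > 0", call. = FALSE)
  # SI: kg, m, s
  M_kg <- M / 1000
  vbar_si <- vbar * 1e-3               # m^3/kg
  rho_si <- .RHO_W20 * 1000            # kg/m^3
  eta_si <- .ETA_W20 * 1e-3            # Pa s
  s_si <- s20w * 1e-13
  f <- M_kg * (1 - vbar_si * rho_si) / (.NA_AVOGADRO * s_si)
  R0 <- (3 * M_kg * vbar_si / (4 * pi * .NA_AVOGADRO))^(1 / 3)
  f0 <- 6 * pi * eta_si * R0
  out <- f / f0
  if (out < 1 - 0.02)
    warning(sprintf("frictional ratio %.3f < 1 is non-physical", out),
            call. = FALSE)
  out
}

#' c(s) sedimentation-coefficient distribution container
#'
#' @param s strictly increasing sedimentation coefficients, S.
#' @param signal non-negative c(s) signal density per S.
#' @param meta optional named list (construction, urea M, ...).
#' @return an object of class `cs_distribution`.
#' @export
cs_distribution <- function(s, signal, meta = list()) {
  .check_finite(s, "s"); .check_finite(signal, "signal")
  if (length(s) != length(signal)) stop("length mismatch", call. = FALSE)
  if (any(diff(s) <= 0)) stop("s must be strictly increasing", call. = FALSE)
  if (any(signal < 0)) stop("signal must be >= 0", call. = FALSE)
  structure(list(s = s, signal = signal, meta = meta),
            class = "cs_distribution")
}

#' @export
print.cs_distribution <- function(x, ...) {
  cat(sprintf("c(s) distribution: %d points, %.1f-%.1f S\n",
              length(x$s), min(x$s), max(x$s)))
  invisible(x)
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

.trapz_window <- function(s, sig, lo, hi) {
  # integrate the piecewise-linear signal exactly over [lo, hi]
  lo <- max(lo, min(s)); hi <- min(hi, max(s))
  if (hi <= lo) return(list(area = 0, mean_s = NA_real_))
  grid <- sort(unique(c(lo, hi, s[s > lo & s < hi])))
  y <- stats::approx(s, sig, grid)$y
  area <- .trapz(grid, y)
  mean_s <- if (area > 0) .trapz(grid, grid * y) / area else NA_real_
  list(area = area, mean_s = mean_s)
}

#' Integrate c(s) peaks into species fractions
#'
#' Trapezoidal integration of the c(s) signal over each window, divided by the
#' integral over the full range, with the signal-weighted mean s inside each
#' window reported as the peak sedimentation coefficient.
#'
#' @param dist a [cs_distribution()].
#' @param boundaries list of `c(s_lo, s_hi)` windows, non-overlapping and
#'   within the s range.
#' @param labels optional character vector of species labels (tetramer,
#'   dimer, monomer, aggregate, ...), recycled to the number of windows.
#' @return data frame with columns `label`, `s_lo`, `s_hi`, `s_peak`
#'   (signal-weighted mean s) and `fraction` of total signal.
#' @export
integrate_cs_peaks <- function(dist, boundaries, labels = NULL) {
  stopifnot(inherits(dist, "cs_distribution"))
  if (!is.list(boundaries)) boundaries <- list(boundaries)
  b <- do.call(rbind, lapply(boundaries, function(w) {
    if (length(w) != 2 || w[2] <= w[1])
      stop("each boundary must be c(s_lo, s_hi) with s_hi > s_lo",
           call. = FALSE)
    w
  }))
  ord <- order(b[, 1])
  if (any(b[ord, 1][-1] < b[ord, 2][-nrow(b)] - 1e-12))
    stop("boundaries overlap", call. = FALSE)
  total <- .trapz(dist$s, dist$signal)
  if (total <= 0) stop("distribution has zero total signal", call. = FALSE)
  rows <- lapply(seq_len(nrow(b)), function(i) {
    w <- .trapz_window(dist$s, dist$signal, b[i, 1], b[i, 2])
    data.frame(s_lo = b[i, 1], s_hi = b[i, 2], s_peak = w$mean_s,
               fraction = w$area / total)
  })
  out <- do.call(rbind, rows)
  out$label <- if (is.null(labels)) sprintf("peak%d", seq_len(nrow(out)))
               else rep_len(labels, nrow(out))
  out[, c("label", "s_lo", "s_hi", "s_peak", "fraction")]
}
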