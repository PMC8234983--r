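# Synthetic-data generators for every input the pipeline consumes: chemical
# and thermal unfolding curves, DSC thermograms, Trp emission spectra and
# c(s) distributions, plus named presets carrying published parameter sets as
# generator truths. Real amplitude/baseline values were never published, so
# the preset baselines are fixed plausible constants (documented in the
# preset) chosen to make the transitions visually comparable to experimental
# curves; they are generator conventions, not measurements.

#' Gaussian noise model
#'
#' @param sigma noise standard deviation. Interpreted as absolute signal
#'   units when `relative = FALSE`, or as a fraction of the native-to-
#'   intermediate amplitude (curve generators) / peak height (DSC, spectra,
#'   c(s)) when `relative = TRUE`.
#' @param relative logical, see `sigma`.
#' @param seed integer seed; identical seeds give identical draws.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, relative = FALSE, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, relative = relative, seed = seed),
            class = "noise_model")
}

.draw_noise <- function(noise, n, scale = 1) {
  stopifnot(inherits(noise, "noise_model"))
  sd <- noise$sigma * if (noise$relative) scale else 1
  if (sd == 0) return(rep(0, n))
  .with_seed(noise$seed, stats::rnorm(n, 0, sd))
}

#' Simulate a chemical (urea) denaturation curve
#'
#' Evaluates the three-state LEM signal ([chem_signal()]) on the grid and adds
#' i.i.d. Gaussian noise. The generator truth is stored in the curve metadata
#' so recovery tests can compare against it.
#'
#' @param thermo a [chem_params()] object.
#' @param baselines a [signal_baselines()] with `x_kind = "chemical"`.
#' @param grid denaturant concentrations, M (default 40 points over 0-7.8 M,
#'   the usual experimental span).
#' @param noise a [noise_model()]; relative sigma is scaled by the
#'   native-to-intermediate amplitude at the first midpoint.
#' @param T evaluation temperature, K.
#' @return a [denaturation_curve()] with `meta$truth`.
#' @export
simulate_chem_curve <- function(thermo, baselines,
                                grid = seq(0, 7.8, length.out = 40),
                                noise = noise_model(0.01, relative = TRUE),
                                T = 298.15) {
  y0 <- chem_signal(grid, thermo, baselines, T)
  amp <- abs((baselines$FI0 + baselines$mI * thermo$Um1) -
             (baselines$FN0 + baselines$mN * thermo$Um1))
  y <- y0 + .draw_noise(noise, length(grid), amp)
  denaturation_curve(grid, y, mode = "chemical",
                     meta = list(truth = thermo, baselines = baselines,
                                 noise = noise))
}

#' Simulate a thermal denaturation curve
#'
#' As [simulate_chem_curve()] for the thermal Gibbs-Helmholtz model; the
#' default grid is 20-90 C at 1 C spacing (a 1 C/min fluorimeter ramp).
#'
#' @param thermo a [thermal_params()] object.
#' @param baselines a [signal_baselines()] with `x_kind = "thermal"`.
#' @param grid absolute temperatures, K.
#' @param noise a [noise_model()]; relative sigma scaled by the
#'   native-to-intermediate amplitude at Tm1.
#' @return a [denaturation_curve()] with `meta$truth`.
#' @export
simulate_thermal_curve <- function(thermo, baselines,
                                   grid = celsius_to_kelvin(seq(20, 90, by = 1)),
                                   noise = noise_model(0.01, relative = TRUE)) {
  y0 <- thermal_signal(grid, thermo, baselines)
  amp <- abs((baselines$FI0 + baselines$mI * thermo$Tm1) -
             (baselines$FN0 + baselines$mN * thermo$Tm1))
  y <- y0 + .draw_noise(noise, length(grid), amp)
  denaturation_curve(grid, y, mode = "thermal",
                     meta = list(truth = thermo, baselines = baselines,
                                 noise = noise))
}

#' Simulate a DSC thermogram
#'
#' Sum of two-state van't Hoff excess heat-capacity peaks
#' ([vanthoff_excess_cp()]) plus a linear drift and Gaussian noise. The
#' result is marked baseline-subtracted and normalized (it is generated
#' directly in molar excess heat-capacity units).
#'
#' @param transitions data frame or list of lists with fields `Tm_C`, `dHvH`
#'   and optionally `amplitude` (default 1); may have zero rows (pure drift).
#' @param drift numeric `c(intercept, slope_per_K)` of the residual baseline.
#' @param noise a [noise_model()]; relative sigma scaled by the tallest peak.
#' @param grid_C temperatures in Celsius (default 20-90 C by 0.1 C).
#' @return a [dsc_thermogram()] with `meta$truth`.
#' @export
simulate_dsc <- function(transitions, drift = c(0, 0),
                         noise = noise_model(0.01, relative = TRUE),
                         grid_C = seq(20, 90, by = 0.1)) {
  Tk <- celsius_to_kelvin(grid_C)
  cp <- drift[1] + drift[2] * (Tk - mean(Tk))
  tr <- if (is.data.frame(transitions)) split(transitions, seq_len(nrow(transitions)))
        else transitions
  peak <- 0
  for (t in tr) {
    a <- if (is.null(t$amplitude)) 1 else t$amplitude
    comp <- a * vanthoff_excess_cp(Tk, celsius_to_kelvin(t$Tm_C), t$dHvH)
    peak <- max(peak, max(comp))
    cp <- cp + comp
  }
  cp <- cp + .draw_noise(noise, length(Tk), if (peak > 0) peak else 1)
  dsc_thermogram(grid_C, cp, normalized = TRUE, baseline_subtracted = TRUE,
                 meta = list(truth = transitions, drift = drift, noise = noise))
}

#' Simulate a tryptophan emission spectrum
#'
#' Log-normal band shape (the standard empirical model for Trp emission,
#' asymmetric with a red tail) parameterized by peak position, FWHM and
#' asymmetry:
#' \deqn{I(\lambda) = A \exp\left[-\frac{\ln 2}{\ln^2\rho}
#'   \ln^2\left(1 + \frac{(\lambda - \lambda_{max})(\rho^2 - 1)}{\rho h}\right)
#'   \right]}
#' (zero where the log argument is non-positive).
#'
#' @param center peak wavelength, nm.
#' @param fwhm full width at half maximum, nm (default 55, typical for Trp).
#' @param amplitude peak intensity, a.u.
#' @param asym asymmetry parameter rho > 1 (default 1.3; red-tailed).
#' @param grid wavelengths, nm (default 300-460 by 1).
#' @param noise a [noise_model()]; relative sigma scaled by `amplitude`.
#' @return an [emission_spectrum()] with `meta$truth`. Negative noisy values
#'   are clipped at 0.
#' @export
simulate_spectrum <- function(center, fwhm = 55, amplitude = 100, asym = 1.3,
                              grid = seq(300, 460, by = 1),
                              noise = noise_model(0.005, relative = TRUE)) {
  if (asym <= 1) stop("asym must be > 1", call. = FALSE)
  arg <- 1 + (grid - center) * (asym^2 - 1) / (asym * fwhm)
  I <- ifelse(arg > 0,
              amplitude * exp(-log(2) / log(asym)^2 * log(pmax(arg, 1e-300))^2),
              0)
  I <- pmax(I + .draw_noise(noise, length(grid), amplitude), 0)
  emission_spectrum(grid, I,
                    meta = list(truth = list(center = center, fwhm = fwhm,
                                             amplitude = amplitude,
                                             asym = asym),
                                noise = noise))
}

#' Simulate a c(s) sedimentation-coefficient distribution
#'
#' Gaussian mixture over sedimentation coefficient; weights are renormalized
#' to sum to one.
#'
#' @param peaks data frame or list of lists with fields `s`, `width` (Gaussian
#'   sd, S) and `weight`.
#' @param grid sedimentation coefficients, S (default 0-20 by 0.02).
#' @param noise a [noise_model()]; relative sigma scaled by the tallest peak.
#' @return a [cs_distribution()] with `meta$truth`. Negative noisy values are
#'   clipped at 0.
#' @export
simulate_cs <- function(peaks, grid = seq(0, 20, by = 0.02),
                        noise = noise_model(0)) {
  pk <- if (is.data.frame(peaks)) split(peaks, seq_len(nrow(peaks))) else peaks
  w <- vapply(pk, function(p) p$weight, 0)
  w <- w / sum(w)
  sig <- 0
  for (i in seq_along(pk))
    sig <- sig + w[i] * stats::dnorm(grid, pk[[i]]$s, pk[[i]]$width)
  sig <- pmax(sig + .draw_noise(noise, length(grid), max(sig)), 0)
  cs_distribution(grid, sig, meta = list(truth = peaks, noise = noise))
}

# ---- presets -------------------------------------------------------------

# Published parameter sets used as generator truths. Baseline/amplitude
# constants are invented generator conventions (source = "preset convention").
.presets <- local({
  chem_bl <- signal_baselines(100, 1.0, 190, 0.0, 120, -1.5,
                              x_kind = "chemical")
  # thermal baselines: native signal declines with temperature (the usual
  # unspecific thermal quenching); values in a.u. against T in Kelvin
  thermal_bl <- signal_baselines(220, -0.40, 286, -0.30, 188, -0.20,
                                 x_kind = "thermal")
  th <- function(t1, t2) thermal_params(celsius_to_kelvin(t1), 80,
                                        celsius_to_kelvin(t2), 120)
  list(
    PAHt_0.8uM_urea = list(
      kind = "chem", thermo = chem_params(2.70, 1.91, 5.48, 2.12),
      baselines = chem_bl,
      source = "global fit, full-length construct, 0.8 uM subunit"),
    PAHt_8uM_urea = list(
      kind = "chem", thermo = chem_params(2.73, 1.23, 6.38, 1.21),
      baselines = chem_bl,
      source = "global fit, full-length construct, 8 uM subunit"),
    PAHd_0.8uM_urea = list(
      kind = "chem", thermo = chem_params(2.59, 2.37, 4.97, 1.02),
      baselines = chem_bl,
      source = "global fit, truncated dimer construct, 0.8 uM subunit"),
    PAHd_8uM_urea = list(
      kind = "chem", thermo = chem_params(4.20, 4.61, 6.54, 2.47),
      baselines = chem_bl,
      source = "global fit, truncated dimer construct, 8 uM subunit"),
    PAHd_0.8uM_thermal = list(
      kind = "thermal", thermo = th(43.1, 54.1), baselines = thermal_bl,
      source = "thermal fit, truncated dimer construct, 0.8 uM subunit"),
    PAHd_5uM_thermal = list(
      kind = "thermal", thermo = th(43.6, 54.1), baselines = thermal_bl,
      source = "thermal fit, truncated dimer construct, 5 uM subunit"),
    PAHt_0.8uM_thermal = list(
      kind = "thermal", thermo = th(46.8, 56.1), baselines = thermal_bl,
      source = "thermal fit, full-length construct, 0.8 uM subunit"),
    PAHt_5uM_thermal = list(
      kind = "thermal", thermo = th(46.7, 56.6), baselines = thermal_bl,
      source = "thermal fit, full-length construct, 5 uM subunit"),
    PAHt_DSC = list(
      kind = "dsc",
      transitions = data.frame(Tm_C = c(44, 55.6), dHvH = c(100, 150),
                               amplitude = 1),
      source = "DSC first-derivative maxima, full-length construct"),
    PAHd_DSC = list(
      kind = "dsc",
      transitions = data.frame(Tm_C = c(45, 54.4), dHvH = c(100, 150),
                               amplitude = 1),
      source = "DSC first-derivative maxima, truncated dimer construct"),
    PAHt_native_spectrum = list(
      kind = "spectrum", center = 330,
      source = "native full-length emission maximum"),
    PAHt_7.6M_urea_spectrum = list(
      kind = "spectrum", center = 355,
      source = "fully unfolded emission maximum (solvent-exposed Trp)"),
    PAHd_native_spectrum = list(
      kind = "spectrum", center = 347,
      source = "native truncated-dimer emission maximum"),
    PAHt_native_AUC = list(
      kind = "cs",
      peaks = data.frame(s = c(9.6, 6.5, 12.8), width = c(0.4, 0.35, 0.6),
                         weight = c(0.81, 0.12, 0.06)),
      source = "native full-length c(s): tetramer 81%, dimer 12%, aggregates 6%")
  )
})

#' Names of the available scenario presets
#' @return character vector of preset names.
#' @export
preset_names <- function() names(.presets)

#' Simulate data from a named scenario preset
#'
#' Presets bundle published thermodynamic parameter sets (urea midpoints and
#' m-values, thermal transition temperatures, DSC transition temperatures,
#' emission maxima, c(s) peak positions/weights) as generator truths together
#' with fixed baseline conventions. The preset's `source` string records
#' where its parameters come from.
#'
#' @param name one of [preset_names()].
#' @param noise optional [noise_model()] overriding the generator default.
#' @param ... further arguments passed to the underlying generator
#'   (e.g. `grid`).
#' @return the simulated object (curve, thermogram, spectrum or
#'   distribution).
#' @examples
#' cv <- simulate_preset("PAHt_0.8uM_urea", noise_model(0))
#' @export
simulate_preset <- function(name, noise = NULL, ...) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; see preset_names()", call. = FALSE)
  p <- .presets[[name]]
  switch(p$kind,
    chem = {
      if (is.null(noise)) noise <- noise_model(0.01, relative = TRUE)
      simulate_chem_curve(p$thermo, p$baselines, noise = noise, ...)
    },
    thermal = {
      if (is.null(noise)) noise <- noise_model(0.01, relative = TRUE)
      simulate_thermal_curve(p$thermo, p$baselines, noise = noise, ...)
    },
    dsc = {
      if (is.null(noise)) noise <- noise_model(0.01, relative = TRUE)
      simulate_dsc(p$transitions, noise = noise, ...)
    },
    spectrum = {
      if (is.null(noise)) noise <- noise_model(0.005, relative = TRUE)
      simulate_spectrum(p$center, noise = noise, ...)
    },
    cs = {
      if (is.null(noise)) noise <- noise_model(0)
      simulate_cs(p$peaks, noise = noise, ...)
    })
}

#' Parameters of a scenario preset
#'
#' @param name one of [preset_names()].
#' @return the preset definition (kind, truth parameters, source string).
#' @export
preset_info <- function(name) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'", call. = FALSE)
  .presets[[name]]
}
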