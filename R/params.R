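# Gas constant in kcal mol^-1 K^-1; fixed so that free energies, m-values and
# enthalpies are always in kcal units. Not user-configurable.
.RGAS <- 1.987204e-3

# Water at 20 C: density g/mL, viscosity mPa s (cP). Reference condition for s20,w.
.RHO_W20 <- 0.99823
.ETA_W20 <- 1.002

.NA_AVOGADRO <- 6.02214076e23

#' Convert between Celsius and Kelvin
#'
#' All internal computation is done in Kelvin; user-facing reports use Celsius.
#'
#' @param x temperature(s) to convert.
#' @return numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'", name, "' must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Thermodynamic parameters of chemical (denaturant) three-state unfolding
#'
#' Bundles the linear-extrapolation-model parameters of a two-transition
#' (native -> intermediate -> unfolded) urea denaturation: the midtransition
#' denaturant concentrations and the m-values (slopes of the transition free
#' energies with denaturant concentration).
#'
#' @param Um1,Um2 midtransition denaturant concentrations (M) of the first
#'   (N -> I) and second (I -> U) transitions. `Um1` must be positive.
#' @param m1,m2 m-values (kcal mol^-1 M^-1); both must be positive.
#' @return an object of class `chem_params`.
#' @examples
#' chem_params(Um1 = 2.70, m1 = 1.91, Um2 = 5.48, m2 = 2.12)
#' @export
chem_params <- function(Um1, m1, Um2, m2) {
  for (nm in c("Um1", "m1", "Um2", "m2")) .check_finite(get(nm), nm)
  if (Um1 <= 0) stop("Um1 must be > 0", call. = FALSE)
  if (m1 <= 0 || m2 <= 0) stop("m-values must be > 0", call. = FALSE)
  structure(list(Um1 = Um1, m1 = m1, Um2 = Um2, m2 = m2),
            class = "chem_params")
}

#' Thermodynamic parameters of thermal three-state unfolding
#'
#' Gibbs-Helmholtz parameters of the two thermal transitions: mid-denaturation
#' temperatures, van't Hoff enthalpy changes at Tm, and (optionally) unfolding
#' heat-capacity changes.
#'
#' @param Tm1,Tm2 mid-denaturation temperatures in Kelvin; `Tm2 >= Tm1`.
#' @param dH1,dH2 unfolding enthalpy changes at the respective Tm
#'   (kcal mol^-1); both positive.
#' @param dCp1,dCp2 unfolding heat-capacity changes (kcal mol^-1 K^-1);
#'   non-negative, default 0 (thermal fits normally keep them fixed at 0
#'   because they are poorly determined by a single fluorescence curve).
#' @return an object of class `thermal_params`.
#' @examples
#' thermal_params(Tm1 = celsius_to_kelvin(43.1), dH1 = 80,
#'                Tm2 = celsius_to_kelvin(54.1), dH2 = 120)
#' @export
thermal_params <- function(Tm1, dH1, Tm2, dH2, dCp1 = 0, dCp2 = 0) {
  for (nm in c("Tm1", "dH1", "Tm2", "dH2", "dCp1", "dCp2"))
    .check_finite(get(nm), nm)
  if (Tm1 <= 0 || Tm2 <= 0) stop("Tm must be > 0 K", call. = FALSE)
  if (Tm2 < Tm1) stop("Tm2 must be >= Tm1", call. = FALSE)
  if (dH1 <= 0 || dH2 <= 0) stop("dH must be > 0", call. = FALSE)
  if (dCp1 < 0 || dCp2 < 0) stop("dCp must be >= 0", call. = FALSE)
  structure(list(Tm1 = Tm1, dH1 = dH1, Tm2 = Tm2, dH2 = dH2,
                 dCp1 = dCp1, dCp2 = dCp2),
            class = "thermal_params")
}

#' Linear signal baselines of the three conformational states
#'
#' The observable (fluorescence intensity) of each state is modelled as a
#' straight line in the perturbation variable x (denaturant concentration in M,
#' or absolute temperature in K): intercept + slope * x.
#'
#' @param FN0,mN intercept and slope of the native-state signal.
#' @param FI0,mI intercept and slope of the intermediate-state signal.
#' @param FU0,mU intercept and slope of the unfolded-state signal.
#' @param x_kind `"chemical"` (slopes per M) or `"thermal"` (slopes per K).
#' @return an object of class `signal_baselines`.
#' @export
signal_baselines <- function(FN0, mN, FI0, mI, FU0, mU,
                             x_kind = c("chemical", "thermal")) {
  x_kind <- match.arg(x_kind)
  for (nm in c("FN0", "mN", "FI0", "mI", "FU0", "mU"))
    .check_finite(get(nm), nm)
  structure(list(FN0 = FN0, mN = mN, FI0 = FI0, mI = mI, FU0 = FU0, mU = mU,
                 x_kind = x_kind),
            class = "signal_baselines")
}

.baseline_matrix <- function(b, x) {
  cbind(N = b$FN0 + b$mN * x, I = b$FI0 + b$mI * x, U = b$FU0 + b$mU * x)
}
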