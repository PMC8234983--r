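#' Transition free energies under the linear extrapolation model
#'
#' Under the linear extrapolation model (LEM) the unfolding free energy of each
#' transition is linear in denaturant concentration:
#' \deqn{\Delta G_1 = m_1 (U_{m1} - D), \quad \Delta G_2 = m_2 (U_{m2} - D).}
#'
#' @param D denaturant concentration(s), M; must be >= 0 and finite.
#' @param thermo a [chem_params()] object.
#' @return a matrix with columns `dG1`, `dG2` (kcal mol^-1), one row per `D`.
#' @examples
#' p <- chem_params(2.70, 1.91, 5.48, 2.12)
#' chem_free_energies(0, p)   # dG1 = 1.91 * 2.70 = 5.157
#' @export
chem_free_energies <- function(D, thermo) {
  stopifnot(inherits(thermo, "chem_params"))
  .check_finite(D, "D")
  if (any(D < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  cbind(dG1 = thermo$m1 * (thermo$Um1 - D),
        dG2 = thermo$m2 * (thermo$Um2 - D))
}

#' Gibbs-Helmholtz unfolding free energy
#'
#' \deqn{\Delta G(T) = \Delta H (1 - T/T_m) +
#'   \Delta C_p [T - T_m - T \ln(T/T_m)]}
#' with \eqn{\Delta H} the unfolding enthalpy at \eqn{T_m}. By construction
#' \eqn{\Delta G(T_m) = 0}.
#'
#' @param T absolute temperature(s), K; > 0.
#' @param Tm mid-denaturation temperature, K.
#' @param dH unfolding enthalpy change at Tm (kcal mol^-1).
#' @param dCp unfolding heat-capacity change (kcal mol^-1 K^-1), default 0.
#' @return free energy change(s), kcal mol^-1.
#' @export
thermal_free_energy <- function(T, Tm, dH, dCp = 0) {
  .check_finite(T, "T"); .check_finite(Tm, "Tm")
  .check_finite(dH, "dH"); .check_finite(dCp, "dCp")
  if (any(T <= 0) || Tm <= 0) stop("temperatures must be > 0 K", call. = FALSE)
  dH * (1 - T / Tm) + dCp * (T - Tm - T * log(T / Tm))
}

#' Boltzmann populations of the three conformational states
#'
#' Given the free energies of the two sequential transitions, returns the molar
#' fractions of native, intermediate and unfolded states,
#' \deqn{f_N = 1/Z,\; f_I = e^{-\Delta G_1/RT}/Z,\;
#'       f_U = e^{-(\Delta G_1+\Delta G_2)/RT}/Z,}
#' with Z the three-term partition sum. Evaluation is done in shifted
#' exponential (log-sum-exp) form so the fractions stay finite and normalized
#' for arbitrarily large |dG| (fits explore extreme parameter values).
#'
#' @param dG1,dG2 transition free energies (kcal mol^-1); recycled together.
#' @param T absolute temperature, K (> 0). Default 298.15 K (25 C).
#' @return a matrix with columns `fN`, `fI`, `fU`; each row sums to 1.
#' @examples
#' species_fractions(0, 0)            # (1/3, 1/3, 1/3)
#' species_fractions(1.0, 2.0)        # mostly native at 25 C
#' @export
species_fractions <- function(dG1, dG2, T = 298.15) {
  .check_finite(dG1, "dG1"); .check_finite(dG2, "dG2"); .check_finite(T, "T")
  if (any(T <= 0)) stop("T must be > 0 K", call. = FALSE)
  n <- max(length(dG1), length(dG2), length(T))
  dG1 <- rep_len(dG1, n); dG2 <- rep_len(dG2, n); T <- rep_len(T, n)
  # log-weights of the three states relative to native
  a <- cbind(0, -dG1 / (.RGAS * T), -(dG1 + dG2) / (.RGAS * T))
  m <- apply(a, 1L, max)
  w <- exp(a - m)
  f <- w / rowSums(w)
  colnames(f) <- c("fN", "fI", "fU")
  f
}

#' Observed signal of the chemical three-state unfolding model
#'
#' The observable is the population-weighted sum of the three linear state
#' baselines, with populations given by the LEM free energies:
#' \deqn{F(D) = f_N F_N(D) + f_I F_I(D) + f_U F_U(D).}
#'
#' @param D denaturant concentration(s), M.
#' @param thermo a [chem_params()] object.
#' @param baselines a [signal_baselines()] object with `x_kind = "chemical"`.
#' @param T evaluation temperature, K (default 298.15 K, the usual 25 C
#'   incubation temperature of urea denaturation experiments).
#' @return fluorescence signal(s), same length as `D`.
#' @export
chem_signal <- function(D, thermo, baselines, T = 298.15) {
  stopifnot(inherits(baselines, "signal_baselines"))
  if (baselines$x_kind != "chemical")
    stop("baselines must have x_kind = 'chemical'", call. = FALSE)
  g <- chem_free_energies(D, thermo)
  f <- species_fractions(g[, "dG1"], g[, "dG2"], T)
  rowSums(f * .baseline_matrix(baselines, D))
}

#' Observed signal of the thermal three-state unfolding model
#'
#' As [chem_signal()], but the perturbation variable is temperature and the
#' transition free energies follow the Gibbs-Helmholtz expression
#' ([thermal_free_energy()]).
#'
#' @param T absolute temperature(s), K.
#' @param thermo a [thermal_params()] object.
#' @param baselines a [signal_baselines()] object with `x_kind = "thermal"`.
#' @return fluorescence signal(s), same length as `T`.
#' @export
thermal_signal <- function(T, thermo, baselines) {
  stopifnot(inherits(thermo, "thermal_params"),
            inherits(baselines, "signal_baselines"))
  if (baselines$x_kind != "thermal")
    stop("baselines must have x_kind = 'thermal'", call. = FALSE)
  dG1 <- thermal_free_energy(T, thermo$Tm1, thermo$dH1, thermo$dCp1)
  dG2 <- thermal_free_energy(T, thermo$Tm2, thermo$dH2, thermo$dCp2)
  f <- species_fractions(dG1, dG2, T)
  rowSums(f * .baseline_matrix(baselines, T))
}
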