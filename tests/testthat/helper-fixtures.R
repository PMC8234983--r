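# Shared fixtures: generator truths and baseline conventions used across tests.

RGAS <- 1.987204e-3   # kcal/mol/K, for independent oracle arithmetic in tests

paht08_truth <- chem_params(Um1 = 2.70, m1 = 1.91, Um2 = 5.48, m2 = 2.12)

chem_bl <- signal_baselines(100, 1.0, 190, 0.0, 120, -1.5, x_kind = "chemical")
thermal_bl <- signal_baselines(220, -0.40, 286, -0.30, 188, -0.20,
                               x_kind = "thermal")

make_chem_curve <- function(thermo = paht08_truth, sigma = 0, seed = 1, ...) {
  simulate_chem_curve(thermo, chem_bl,
                      noise = noise_model(sigma, relative = TRUE, seed = seed),
                      ...)
}

make_thermal_curve <- function(Tm1_C = 43.1, Tm2_C = 54.1, sigma = 0,
                               seed = 1, ...) {
  th <- thermal_params(celsius_to_kelvin(Tm1_C), 80,
                       celsius_to_kelvin(Tm2_C), 120)
  simulate_thermal_curve(th, thermal_bl,
                         noise = noise_model(sigma, relative = TRUE,
                                             seed = seed), ...)
}

# independent direct evaluation of the three-state Boltzmann weights,
# bypassing the package's log-sum-exp path
naive_fractions <- function(dG1, dG2, T = 298.15) {
  w <- c(1, exp(-dG1 / (RGAS * T)), exp(-(dG1 + dG2) / (RGAS * T)))
  w / sum(w)
}
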