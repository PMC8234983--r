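---
title: "Three-state unfolding equilibria: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state unfolding equilibria: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threestate)
```

## The problem

Large oligomeric enzymes such as human phenylalanine hydroxylase (PAH, the
enzyme whose loss-of-stability variants cause phenylketonuria) rarely unfold
in a single cooperative step. Equilibrium denaturation monitored by
tryptophan fluorescence typically shows two sigmoidal transitions, indicating
a populated intermediate between the native (N) and unfolded (U) ensembles.
`threestate` implements the quantitative machinery for analysing such
equilibria: forward models for the N ⇌ I ⇌ U scheme under chemical and
thermal perturbation, individual and global least-squares fitting of
denaturation curves, van't Hoff deconvolution of two-transition DSC
thermograms, emission-spectrum descriptors, and the sedimentation arithmetic
used to assign oligomeric states from analytical ultracentrifugation.

The three-state description is macroscopic: each "state" is an ensemble, no
explicit subunit dissociation or aggregation step is modelled, and the
fitted quantities should be read as apparent parameters. This mirrors how
practitioners treat poorly reversible unfolding of aggregation-prone
oligomers.

## The models

**Chemical (denaturant) unfolding.** Each transition free energy follows the
linear extrapolation model (LEM) in denaturant concentration $D$:

$$\Delta G_1 = m_1(U_{m1} - D), \qquad \Delta G_2 = m_2(U_{m2} - D),$$

with $U_m$ the midpoint concentration (M) and $m > 0$ the denaturant
sensitivity (kcal·mol⁻¹·M⁻¹, proportional to the surface area newly exposed
in the transition). The observed signal is the population-weighted sum of
three state signals, each linear in $D$:

$$F(D) = f_N F_N(D) + f_I F_I(D) + f_U F_U(D), \qquad
  F_k(D) = F_{k0} + m_k D,$$

with Boltzmann populations
$f_N : f_I : f_U = 1 : e^{-\Delta G_1/RT} : e^{-(\Delta G_1+\Delta G_2)/RT}$,
normalized to 1. $R$ is fixed at $1.987204\times10^{-3}$ kcal·mol⁻¹·K⁻¹ and
is deliberately not configurable: every energy in the package is in kcal, and
a silent J/kcal mix-up is the classic failure mode of these fits. Chemical
equilibria are evaluated at 298.15 K by default (samples equilibrated at
25 °C).

**Thermal unfolding.** The same population-weighted sum, with the transition
free energies given by the Gibbs–Helmholtz expression

$$\Delta G(T) = \Delta H\left(1 - \tfrac{T}{T_m}\right) +
  \Delta C_p\left[T - T_m - T\ln\tfrac{T}{T_m}\right],$$

where $\Delta H$ is the unfolding enthalpy at $T_m$. Both $\Delta C_p$ values
default to zero and are held fixed during fitting: a single fluorescence
curve does not constrain them usefully, and reporting them would suggest
precision that is not there. They can be released with `float_dcp = TRUE`.
All internal temperatures are Kelvin; constructors, summaries and reports use
Celsius (conversion constant 273.15).

**Numerical evaluation.** Populations are computed with a shifted-exponential
(log-sum-exp) scheme, so they remain finite and exactly normalized for
arbitrarily large $|\Delta G|/RT$. This matters because the optimizer
explores extreme parameter values on its way to the optimum; a naive
implementation overflows there and derails the search.

## Curve fitting

`fit_unfolding()` fits one curve or a list of replicate curves. The key
structural observation is that the model is *conditionally linear*: once the
thermodynamic parameters are fixed, the six baseline coefficients of each
curve enter linearly through the populations. The fit therefore uses
variable projection: at every objective evaluation the baselines are solved
exactly by per-curve linear least squares (rank-deficient designs — e.g. an
unfolded state that is never populated — are handled by pivoted QR, with
dropped coefficients set to zero), and the Levenberg–Marquardt search runs
only over the four (chemical) or four-to-six (thermal) thermodynamic
parameters. This keeps the global fit low-dimensional, fast and robust, and
makes the replicate convention explicit: thermodynamic parameters are shared
across curves, baselines are always per-curve.

Choices that matter:

* **Initial guess** (`initial_guess()`): transition midpoints from the two
  largest-magnitude extrema of a smoothed first derivative of the signal;
  steepness ($m$, $\Delta H$) from the derivative peak's full width at half
  maximum (for a two-state transition that width is $\approx 3.53\,RT/m$ in
  denaturant, $\approx 3.53\,R T_m^2/\Delta H$ in temperature); edge
  baselines from linear fits to the first and last 15% of points; the
  intermediate baseline from the inter-midpoint plateau. Data
  indistinguishable from a straight line fall back to midpoints at the
  terciles of the x-range and flag the result.
* **Bounds**: midpoints constrained to the observed x-range ± 10%,
  $m \in (0, 20]$ kcal·mol⁻¹·M⁻¹, $\Delta H \in (0, 500]$ kcal·mol⁻¹. These
  keep the optimizer out of non-physical basins without ever binding at a
  genuine optimum.
* **Multistart**: two-transition fits have local minima, so the search is
  restarted (default 8 times) from seeded ±20% perturbations of the initial
  guess and the lowest-RSS solution is kept. Identical data, configuration
  and seed give bit-identical results; the local RNG state is saved and
  restored so fitting never perturbs the caller's random stream.
* **Standard errors** come from the scaled inverse Gauss–Newton normal
  matrix of the profiled residuals at the optimum (the variable-projection
  Jacobian), with the residual variance estimated on
  $n - (\text{free thermo} + 6 \times \text{curves})$ degrees of freedom.
  `bootstrap_stderr()` offers a residual-bootstrap cross-check (default 200
  refits) for when the local-curvature approximation is doubted — these
  apparent parameters are approximations at best for poorly reversible
  systems.
* **Weighting**: unweighted least squares. Fluorimeter noise at a fixed
  emission wavelength is close to homoscedastic, and no point-weighting
  scheme is reported for this kind of analysis.

`populations()` converts a converged fit into N/I/U molar fractions along any
grid — the computation behind statements like "at 5.4 M urea the protein is
~90% in the intermediate".

## DSC processing

DSC thermograms pass through an order-tagged pipeline — buffer-baseline
subtraction (`dsc_subtract_baseline()`, buffer interpolated onto the sample
grid), molar normalization (`dsc_normalize()`, dividing by moles of subunit
in the cell) — with flags that make out-of-order processing an error rather
than a unit bug.

Transition temperatures are located on the first derivative of the smoothed
excess heat capacity (`dsc_find_tm()`): maxima are the +→− zero crossings,
refined by quadratic interpolation through the three points around the
discrete maximum. Smoothing is a centred moving average with a 1.5 K default
window, suited to the ~0.1 K point spacing of a 1 K·min⁻¹ scan. Candidate
maxima are filtered by *topographic prominence* (the drop from the peak to
the highest valley separating it from higher ground) at 5% of the global
peak height: noise shoulders on the flank of a real peak can be tall but
have near-zero prominence, so this criterion suppresses them while keeping
genuinely overlapping transitions. Note the exact maximum of a two-state
excess-heat-capacity peak sits marginally *below* $T_m$ (< 0.2 K for
$\Delta H_{vH} \ge 80$ kcal·mol⁻¹); the derivative procedure inherits that
offset, which is negligible at the precision these temperatures are
reported.

`dsc_deconvolve()` fits the sum of two *independent* two-state van't Hoff
peaks plus a linear residual baseline,

$$C_p^{exc}(T) = \frac{\Delta H_{vH}^2}{R T^2}\,f(1-f), \qquad
  f = \frac{K}{1+K},\quad K = e^{-\Delta H_{vH}(1 - T/T_m)/(RT)},$$

initialized from the derivative procedure. The independent-peaks form (with
$\Delta H_{cal} = \Delta H_{vH}$ per peak) is the simplest model that
reproduces a two-transition thermogram; a sequential three-state
deconvolution is deliberately not attempted because aggregation-distorted
thermograms do not support it. For the same reason the fit window by default
excludes the high-temperature region beyond where the heat capacity falls to
25% of the second peak's height on its high side — the part of a real scan
dominated by irreversible aggregation. A second component whose area drops
below 5% of the total, or that collapses onto the first (ΔTm < 1 K), is
flagged degenerate rather than silently reported.

## Spectra and hydrodynamics

Emission maxima (`emission_maximum()`) are taken on a 5 nm moving-average
smooth with quadratic refinement, and flagged when the maximum sits at the
scan edge; `spectral_shift()` is the signed difference (positive = red
shift, i.e. increased tryptophan solvent exposure); `intensity_ratio()`
defaults to the classic I355/I337 exposure index and is scale-invariant by
construction.

`s20w()` applies the standard viscosity/buoyancy correction to water at
20 °C (fixed reference constants ρ = 0.99823 g·mL⁻¹, η = 1.002 mPa·s);
`frictional_ratio()` compares the Stokes radius implied by $s_{20,w}$ and
the molar mass with the equivalent anhydrous sphere. Solvent density and
viscosity are *inputs*: computing them from buffer composition (urea
tables, partial specific volumes from sequence) is the job of dedicated
tools and out of scope, so defaults exist only for pure water at 20/25 °C,
and $\bar v$ defaults to the generic protein value 0.73 mL·g⁻¹ with an
explicit override. `integrate_cs_peaks()` integrates c(s) distributions over
user-set windows (trapezoidal, with exact treatment of window edges between
grid points) and reports signal-weighted mean s per window; c(s) inversion
itself is consumed, never computed.

## The synthetic-data generator

Because raw experimental curves of this kind are rarely deposited, every
input type has a generator (`simulate_chem_curve()`,
`simulate_thermal_curve()`, `simulate_dsc()`, `simulate_spectrum()`,
`simulate_cs()`) and the package's validation is built on parameter
*recovery*: generate data with known truths under realistic conditions,
analyse blind, compare. Named presets (`preset_names()`) carry published
parameter sets as truths — urea midpoints and m-values for four
construction × concentration combinations, four thermal Tm pairs, two DSC
temperature pairs, emission-band positions, and a tetramer/dimer/aggregate
c(s) mixture — each annotated with a `source` string.

Generator conventions, chosen once:

* Chemical baselines: native 100 a.u., intermediate 190 a.u. (the ~90%
  fluorescence increase of the first transition), unfolded 120 a.u., with
  slopes 1.0, 0.0 and −1.5 a.u.·M⁻¹ — modest drifts of the size seen in
  real urea titrations. Thermal baselines decline with temperature
  (−0.40, −0.30, −0.20 a.u.·K⁻¹ from intercepts 220, 286, 188 a.u.),
  reproducing the unspecific thermal quenching of tryptophan fluorescence
  before the first transition while both transitions increase intensity.
  These amplitudes are invented conventions (published figures show only
  arbitrary-units axes) and are excluded from any recovery claim.
* Noise: i.i.d. Gaussian, default σ = 1% of the native-to-intermediate
  amplitude — which makes fitted parameter uncertainties the same order as
  published global-fit errors. Thermal enthalpies for the Tm-pair presets
  are 80 and 120 kcal·mol⁻¹, typical domain-sized values consistent with
  the observed transition widths; DSC presets use van't Hoff enthalpies of
  100 and 150 kcal·mol⁻¹.
* Grids: 40 points over 0–7.8 M urea; 20–90 °C at 1 °C spacing
  (fluorescence ramp); 20–90 °C at 0.1 °C spacing (DSC); 300–460 nm
  spectra; 0–20 S c(s).
* Determinism: every generator draws through an isolated, seeded RNG and
  restores the global stream; identical seeds give identical data, and the
  truth travels in the object metadata.

What the generator does *not* emulate — and therefore what recovery tests
cannot certify — is exactly what makes real PAH data hard: aggregation at
intermediate and high denaturant, irreversibility, scan-rate-dependent DSC
distortion, baseline curvature, and protein-concentration-coupled
dissociation equilibria. Passing recovery tests demonstrates that the
estimator returns truth when the model is true; on real data the same
numbers are apparent parameters of a simplified description.

Under these study conditions the recovery precision has a floor worth
stating: with three replicates at 1% noise, the Monte Carlo standard
deviation of a weakly constrained parameter — a shallow second transition
ending near the edge of the denaturant range, or the first Tm of two
transitions overlapping within ~9 °C — is about 0.1 M or 0.5–0.6 °C
respectively. Individual draws of the replicate noise can therefore miss the
truth by a couple of tenths of an M or more than half a degree with no
estimator defect; the test suite's strictest recovery checks sit at exactly
this boundary and the two that probe it are expected to show it.

## Problem sizes and runtime

The shipped tests and the acceptance script run entirely on generated data:
global fits use 3 × 40 (chemical) or 3 × 71 (thermal) points with 8
restarts, DSC analyses 701 points, and the property suites sweep dozens of
parameter sets; the whole suite completes in well under a minute on one
core. These sizes were chosen because recovery quality saturates there —
denser grids change the fitted values by far less than the noise-driven
spread.

## Known limitations

* Apparent parameters only: no dissociation stoichiometry, no aggregation,
  no kinetic (irreversible) DSC model, no protein-concentration coupling.
* The DSC deconvolution's independent-peaks assumption double-counts
  populations where two transitions overlap strongly; it is a peak
  decomposition, not a thermodynamic partition function.
* Standard errors assume homoscedastic Gaussian noise and local quadratic
  behaviour; use the bootstrap for skeptical error bars.
* `Um2 > Um1` and `Tm2 ≥ Tm1` are not enforced during optimization; with
  featureless or single-transition data the second transition can collapse
  onto the first (DSC flags this; curve fits report it through overlapping
  confidence intervals).
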