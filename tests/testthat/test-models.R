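test_that("LEM free energies are linear in denaturant and match hand arithmetic", {
  p <- paht08_truth
  g <- chem_free_energies(c(0, p$Um1, 4), p)
  expect_equal(unname(g[2, "dG1"]), 0)                       # zero at the midpoint
  expect_equal(unname(g[1, "dG1"]), 1.91 * 2.70)             # 5.157 kcal/mol at 0 M
  expect_equal(unname(g[3, "dG2"]), 2.12 * (5.48 - 4.0))     # 3.1376 kcal/mol
  # linearity in D
  D <- seq(0, 7.8, length.out = 9)
  gg <- chem_free_energies(D, p)
  expect_equal(diff(gg[, "dG1"]) / diff(D), rep(-p$m1, 8))
  expect_error(chem_free_energies(-1, p), "must be >= 0")
  expect_error(chem_free_energies(NaN, p), "finite")
})

test_that("species fractions match direct Boltzmann evaluation and normalize", {
  expect_equal(drop(species_fractions(0, 0)), c(fN = 1, fI = 1, fU = 1) / 3)
  f <- drop(species_fractions(0, 50))
  expect_equal(unname(f[1:2]), c(0.5, 0.5), tolerance = 1e-10)
  expect_lt(f[3], 1e-12)
  # frozen high-precision oracle value
  expect_equal(drop(species_fractions(1.0, 2.0, 298.15)),
               c(fN = 0.839455378238, fI = 0.155235996496,
                 fU = 0.00530862526620),
               tolerance = 1e-9)
  # normalization to 1e-12 over a sweep of magnitudes, both signs
  set.seed(42)
  for (i in 1:50) {
    g <- stats::runif(2, -30, 30) * 10^sample(-1:2, 1)
    f <- species_fractions(g[1], g[2], stats::runif(1, 250, 400))
    expect_lt(abs(sum(f) - 1), 1e-12)
    expect_true(all(is.finite(f)))
  }
  expect_error(species_fractions(1, 1, T = -5), "> 0")
})

test_that("log-space evaluation agrees with naive weights and survives overflow", {
  for (g1 in c(-5, 0, 2, 10)) for (g2 in c(-3, 0, 4)) {
    expect_equal(unname(drop(species_fractions(g1, g2))),
                 naive_fractions(g1, g2), tolerance = 1e-12)
  }
  # naive exponentials overflow here; the log-sum-exp path must not
  f <- drop(species_fractions(-600, -600, 298.15))
  expect_true(all(is.finite(f)))
  expect_equal(unname(f[3]), 1, tolerance = 1e-12)
})

test_that("chemical signal is the population-weighted baseline sum", {
  p <- paht08_truth
  flat <- signal_baselines(7, 0, 7, 0, 7, 0)
  expect_equal(chem_signal(seq(0, 7.8, 0.5), p, flat), rep(7, 16))
  # at Um1 with the second transition far away: halfway between N and I
  far <- chem_params(2.7, 1.91, 30, 2.12)
  bl <- signal_baselines(1, 0, 2, 0, 10, 0)
  expect_equal(chem_signal(2.7, far, bl), 1.5, tolerance = 1e-4)
  # frozen brute-force oracle for the published first-row parameters
  expect_equal(chem_signal(4.0, p, signal_baselines(1, 0, 2, 0, 1.5, 0)),
               1.98270793429, tolerance = 1e-9)
  expect_error(chem_signal(1, p, thermal_bl), "x_kind")
})

test_that("chemical signal is affine-invariant in the baselines", {
  p <- paht08_truth
  D <- seq(0, 7.8, length.out = 25)
  a <- 3.7; b <- -11
  bl2 <- signal_baselines(a * chem_bl$FN0 + b, a * chem_bl$mN,
                          a * chem_bl$FI0 + b, a * chem_bl$mI,
                          a * chem_bl$FU0 + b, a * chem_bl$mU)
  expect_equal(chem_signal(D, p, bl2), a * chem_signal(D, p, chem_bl) + b,
               tolerance = 1e-12)
})

test_that("three-state signal collapses to a two-state sigmoid when the second transition is remote", {
  Um1 <- 2; m1 <- 2; m2 <- 2; Um2 <- 12   # separation 10 M >> 20 RT/m2
  p <- chem_params(Um1, m1, Um2, m2)
  bl <- signal_baselines(1, 0.2, 3, -0.1, 50, 0)
  D <- seq(0, 3, 0.2)
  K <- exp(-m1 * (Um1 - D) / (RGAS * 298.15))     # independent two-state form
  two_state <- ((bl$FN0 + bl$mN * D) + (bl$FI0 + bl$mI * D) * K) / (1 + K)
  expect_equal(chem_signal(D, p, bl), two_state, tolerance = 1e-9)
})

test_that("Gibbs-Helmholtz free energy has the right fixed points and slope", {
  expect_equal(thermal_free_energy(320, 320, 100, 0.5), 0)   # dG(Tm) = 0
  expect_equal(thermal_free_energy(310, 320, 100, 0), 3.125) # 100*(1-310/320)
  expect_equal(thermal_free_energy(seq(280, 360, 10), 320, 0, 0), rep(0, 9))
  # strictly decreasing around Tm for dH > 0 (with and without dCp)
  Tg <- seq(310, 330, 0.5)
  for (dcp in c(0, 1.5))
    expect_true(all(diff(thermal_free_energy(Tg, 320, 90, dcp)) < 0))
  expect_error(thermal_free_energy(-1, 320, 100), "> 0")
})

test_that("thermal signal reproduces midpoint, native limit and frozen oracle value", {
  th <- thermal_params(316.25, 80, 380, 300)   # second transition remote
  bl <- signal_baselines(10, 0, 20, 0, 99, 0, x_kind = "thermal")
  expect_equal(thermal_signal(316.25, th, bl), 15, tolerance = 1e-3)
  # native limit far below Tm1
  bl2 <- signal_baselines(10, 0.05, 200, 0, 99, 0, x_kind = "thermal")
  expect_equal(thermal_signal(280, th, bl2), 10 + 0.05 * 280, tolerance = 1e-6)
  # frozen brute-force oracle
  th2 <- thermal_params(316.25, 80, 327.25, 120)
  expect_equal(thermal_signal(321, th2,
                              signal_baselines(10, 0, 18, 0, 25, 0,
                                               x_kind = "thermal")),
               17.1322137578, tolerance = 1e-9)
  expect_error(thermal_signal(300, th, chem_bl), "x_kind")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(chem_params(-1, 2, 5, 2), "Um1")
  expect_error(chem_params(2, -2, 5, 2), "m-values")
  expect_error(thermal_params(330, 80, 320, 120), "Tm2")
  expect_error(thermal_params(320, -80, 330, 120), "dH")
  expect_error(signal_baselines(1, Inf, 2, 0, 3, 0), "finite")
})
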