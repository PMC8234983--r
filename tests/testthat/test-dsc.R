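make_raw_thermogram <- function(cp_fun, grid_C = seq(20, 90, 0.1), ...) {
  dsc_thermogram(grid_C, cp_fun(celsius_to_kelvin(grid_C)), ...)
}

test_that("buffer subtraction works pointwise on the sample grid", {
  peak <- function(Tk) vanthoff_excess_cp(Tk, celsius_to_kelvin(50), 120)
  drift <- function(Tk) 2 + 0.05 * (Tk - 330)
  sample <- make_raw_thermogram(function(Tk) peak(Tk) + drift(Tk))
  same <- make_raw_thermogram(function(Tk) peak(Tk) + drift(Tk))
  zero <- dsc_subtract_baseline(sample, same)
  expect_equal(zero$cp, rep(0, length(zero$cp)))
  expect_true(zero$baseline_subtracted)

  # constant buffer shifts by -c; coarse buffer grid exercises interpolation
  const <- make_raw_thermogram(function(Tk) rep(3, length(Tk)))
  shifted <- dsc_subtract_baseline(sample, const)
  expect_equal(shifted$cp, sample$cp - 3)

  buffer <- make_raw_thermogram(drift, grid_C = seq(15, 95, 0.7))
  rec <- dsc_subtract_baseline(sample, buffer)
  expect_equal(rec$cp, peak(celsius_to_kelvin(seq(20, 90, 0.1))),
               tolerance = 1e-6)

  narrow <- make_raw_thermogram(drift, grid_C = seq(30, 60, 0.5))
  expect_error(dsc_subtract_baseline(sample, narrow), "cover")
})

test_that("molar normalization divides by moles in the cell and is order-guarded", {
  raw <- make_raw_thermogram(function(Tk) rep(1e-8, length(Tk)),
                             baseline_subtracted = TRUE)
  n5 <- dsc_normalize(raw, conc = 5, cell_volume = 0.5)
  expect_equal(n5$cp, rep(1e-8 / 2.5e-9, length(raw$cp)))  # 5 uM * 0.5 mL
  n10 <- dsc_normalize(raw, conc = 10, cell_volume = 0.5)
  expect_equal(n10$cp, n5$cp / 2)
  expect_error(dsc_normalize(n5, 5, 0.5), "already normalized")
  unsub <- make_raw_thermogram(function(Tk) rep(1, length(Tk)))
  expect_error(dsc_normalize(unsub, 5, 0.5), "subtract")
  expect_error(dsc_find_tm(unsub), "normalize")
})

test_that("normalization round-trips the generator's molar amplitude", {
  truth <- data.frame(Tm_C = 50, dHvH = 120)
  molar <- simulate_dsc(truth, noise = noise_model(0))
  moles <- 5e-6 * 0.5e-3
  raw <- dsc_thermogram(kelvin_to_celsius(molar$T), molar$cp * moles,
                        baseline_subtracted = TRUE)
  back <- dsc_normalize(raw, conc = 5, cell_volume = 0.5)
  expect_equal(back$cp, molar$cp, tolerance = 1e-12)
})

test_that("first-derivative Tm detection matches the dense-grid argmax", {
  tg <- simulate_dsc(data.frame(Tm_C = 50, dHvH = 120), noise = noise_model(0))
  tm <- dsc_find_tm(tg)
  expect_length(tm, 1)
  expect_lt(abs(tm - 50), 0.15)
  # independent dense-grid oracle: the cp maximum sits marginally below Tm
  Tc <- seq(45, 55, 1e-4)
  oracle <- Tc[which.max(vanthoff_excess_cp(celsius_to_kelvin(Tc),
                                            celsius_to_kelvin(50), 120))]
  expect_lt(abs(tm - oracle), 0.05)

  two <- simulate_dsc(data.frame(Tm_C = c(40, 70), dHvH = c(120, 120)),
                      noise = noise_model(0))
  tms <- dsc_find_tm(two)
  expect_length(tms, 2)
  expect_true(all(diff(tms) > 0))
  expect_equal(tms, c(40, 70), tolerance = 0.1)

  flatline <- dsc_thermogram(seq(20, 90, 0.1), rep(0, 701), normalized = TRUE,
                             baseline_subtracted = TRUE)
  expect_length(dsc_find_tm(flatline), 0)
})

test_that("the two-state cp maximum sits within 0.2 K of Tm for dHvH >= 80", {
  Tc <- seq(40, 60, 1e-4)
  for (dh in c(80, 120, 200)) {
    argmax <- Tc[which.max(vanthoff_excess_cp(celsius_to_kelvin(Tc),
                                              celsius_to_kelvin(50), dh))]
    expect_lt(50 - argmax, 0.2)
    expect_gte(50 - argmax, 0)
  }
})

test_that("van't Hoff excess heat capacity peaks at Tm and integrates to dHvH", {
  Tm <- celsius_to_kelvin(50); dh <- 120
  # at Tm the transition is half complete: cp = dHvH^2 / (4 R Tm^2)
  expect_equal(vanthoff_excess_cp(Tm, Tm, dh), dh^2 / (4 * RGAS * Tm^2))
  # tails vanish far from Tm
  expect_lt(vanthoff_excess_cp(Tm - 40, Tm, dh), 1e-4)
  expect_lt(vanthoff_excess_cp(Tm + 40, Tm, dh), 1e-3)
  # quadrature oracle: integral over +/- 30 K approximates dHvH within 1%
  area <- stats::integrate(vanthoff_excess_cp, Tm - 30, Tm + 30,
                           Tm = Tm, dHvH = dh)$value
  expect_equal(area, dh, tolerance = 0.01)
  expect_true(all(vanthoff_excess_cp(seq(280, 380, 0.5), Tm, dh) >= 0))
})

test_that("noiseless two-peak deconvolution recovers both transitions to 1e-3", {
  truth <- data.frame(Tm_C = c(44, 55.6), dHvH = c(100, 150))
  tg <- simulate_dsc(truth, noise = noise_model(0))
  d <- dsc_deconvolve(tg, cut = NULL, seed = 1)
  expect_true(d$converged)
  expect_false(any(d$transitions$degenerate))
  expect_equal(celsius_to_kelvin(d$transitions$Tm_C),
               celsius_to_kelvin(truth$Tm_C), tolerance = 1e-3)
  expect_equal(d$transitions$dHvH, truth$dHvH, tolerance = 1e-3)
})

test_that("two-transition deconvolution beats any single-transition fit on two-peak data", {
  tg <- simulate_preset("PAHd_DSC", noise_model(0.01, TRUE, seed = 3))
  d <- dsc_deconvolve(tg, seed = 1)
  # independent single-peak least squares on the same fitting window
  keepT <- tg$T >= celsius_to_kelvin(d$window_C[1]) &
           tg$T <= celsius_to_kelvin(d$window_C[2])
  Tf <- tg$T[keepT]; cpf <- tg$cp[keepT]
  single <- function(p) sum((cpf - p[3] *
    vanthoff_excess_cp(Tf, p[1], p[2]) - p[4])^2)
  best_single <- Inf
  for (tm0 in celsius_to_kelvin(c(45, 50, 54.4)))
    best_single <- min(best_single,
                       stats::optim(c(tm0, 120, 1, 0), single,
                                    method = "Nelder-Mead",
                                    control = list(maxit = 2000))$value)
  expect_lt(d$rss, best_single)
})

test_that("a single-peak thermogram fitted with two transitions flags the degenerate one", {
  tg <- simulate_dsc(data.frame(Tm_C = 50, dHvH = 120),
                     noise = noise_model(0.005, TRUE, seed = 2))
  d <- dsc_deconvolve(tg, seed = 1)
  expect_true(d$converged)
  expect_true(any(d$transitions$degenerate))
})
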