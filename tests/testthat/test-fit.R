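test_that("initial guess locates transition midpoints from the derivative", {
  cv <- make_chem_curve()
  g <- initial_guess(cv)
  expect_false(g$fallback)
  expect_lt(abs(g$thermo[["Um1"]] - 2.70), 0.5)
  expect_lt(abs(g$thermo[["Um2"]] - 5.48), 0.5)

  tv <- make_thermal_curve(43.1, 54.1)
  gt <- initial_guess(tv)
  expect_lt(abs(kelvin_to_celsius(gt$thermo[["Tm1"]]) - 43.1), 2)
  expect_lt(abs(kelvin_to_celsius(gt$thermo[["Tm2"]]) - 54.1), 2)
})

test_that("featureless data falls back to tercile midpoints with a flag", {
  x <- seq(0, 7.8, length.out = 30)
  cv <- denaturation_curve(x, 5 + 0.1 * x, mode = "chemical")
  g <- initial_guess(cv)
  expect_true(g$fallback)
  expect_equal(unname(g$thermo[c("Um1", "Um2")]), c(2.6, 5.2), tolerance = 1e-6)
})

test_that("noiseless curves are recovered to 1e-4 relative error", {
  f <- fit_unfolding(make_chem_curve(), multistart = 2, seed = 1)
  expect_true(f$converged)
  truth <- unlist(paht08_truth)
  expect_equal(unname(coef(f)[names(truth)]), unname(truth),
               tolerance = 1e-4)
  # per-curve baselines recovered too
  b <- f$baselines[[1]]
  expect_equal(b$FN0, 100, tolerance = 1e-3)
  expect_equal(b$mU, -1.5, tolerance = 1e-3)

  ft <- fit_unfolding(make_thermal_curve(43.1, 54.1), multistart = 2, seed = 1)
  expect_true(ft$converged)
  expect_equal(unname(coef(ft)[c("Tm1", "dH1", "Tm2", "dH2")]),
               c(celsius_to_kelvin(43.1), 80, celsius_to_kelvin(54.1), 120),
               tolerance = 1e-4)
})

test_that("fits are affine-invariant: scaling the signal rescales only baselines", {
  cv <- make_chem_curve(sigma = 0.01, seed = 3)
  cv10 <- denaturation_curve(cv$x, 10 * cv$y, mode = "chemical")
  f1 <- fit_unfolding(cv, multistart = 1)
  f10 <- fit_unfolding(cv10, multistart = 1)
  expect_equal(coef(f10), coef(f1), tolerance = 1e-6)
  expect_equal(f10$baselines[[1]]$FI0, 10 * f1$baselines[[1]]$FI0,
               tolerance = 1e-6)
  expect_equal(f10$baselines[[1]]$mN, 10 * f1$baselines[[1]]$mN,
               tolerance = 1e-6)
})

test_that("a one-curve global fit reduces to the individual fit", {
  cv <- make_chem_curve(sigma = 0.01, seed = 5)
  fi <- fit_unfolding(cv, multistart = 3, seed = 2)
  fg <- fit_unfolding(list(cv), multistart = 3, seed = 2)
  expect_equal(coef(fg), coef(fi), tolerance = 1e-8)
  expect_equal(fg$rss, fi$rss, tolerance = 1e-8)
})

test_that("global fits are permutation-invariant and seed-deterministic", {
  cvs <- lapply(1:3, function(s) make_chem_curve(sigma = 0.01, seed = s))
  f1 <- fit_unfolding(cvs, multistart = 2, seed = 7)
  f2 <- fit_unfolding(cvs[c(3, 1, 2)], multistart = 2, seed = 7)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  # bit-identical rerun under the same config + seed
  f3 <- fit_unfolding(cvs, multistart = 2, seed = 7)
  expect_identical(coef(f3), coef(f1))
  expect_identical(f3$rss, f1$rss)
})

test_that("pooling replicates does not inflate shared-parameter errors", {
  for (s in c(1, 11)) {
    one <- fit_unfolding(make_chem_curve(sigma = 0.01, seed = s),
                         multistart = 2, seed = 1)
    three <- fit_unfolding(lapply(s + 0:2, function(k)
      make_chem_curve(sigma = 0.01, seed = k)), multistart = 2, seed = 1)
    for (p in c("Um1", "Um2"))
      expect_lte(three$stderr[[p]], one$stderr[[p]] * 1.05)
  }
})

test_that("mixed-mode curve lists are rejected", {
  expect_error(fit_unfolding(list(make_chem_curve(), make_thermal_curve())),
               "mixed mode")
})

test_that("thermal fits hold dCp at zero unless released", {
  tv <- make_thermal_curve(43.1, 54.1, sigma = 0.005, seed = 2)
  f <- fit_unfolding(tv, multistart = 1)
  expect_identical(unname(coef(f)[c("dCp1", "dCp2")]), c(0, 0))
  expect_true(all(is.na(f$stderr[c("dCp1", "dCp2")])))
})

test_that("populations from a converged fit normalize and reach the unfolded limit", {
  f <- fit_unfolding(make_chem_curve(), multistart = 1)
  grid <- seq(0, 12, 0.5)
  pop <- populations(f, grid)
  expect_true(all(abs(rowSums(pop) - 1) < 1e-12))
  expect_gt(pop[nrow(pop), "fU"], 0.999)       # far past Um2
  # at Um1 with a remote second transition: fN = fI
  f2 <- fit_unfolding(make_chem_curve(chem_params(2.7, 1.91, 30, 2.12),
                                      grid = seq(0, 7.8, length.out = 40)),
                      multistart = 1)
  p2 <- populations(f2, coef(f2)[["Um1"]])
  expect_equal(unname(p2[, "fN"]), unname(p2[, "fI"]), tolerance = 1e-3)
})

test_that("predict returns signals on the fitted baselines and fractions on demand", {
  cv <- make_chem_curve()
  f <- fit_unfolding(cv, multistart = 1)
  expect_equal(predict(f), cv$y, tolerance = 1e-6)
  fr <- predict(f, newdata = c(1, 4, 7), type = "fractions")
  expect_equal(dim(fr), c(3L, 3L))
  expect_equal(rowSums(fr), rep(1, 3))
})

test_that("residual bootstrap errors are the same order as curvature errors", {
  cv <- make_chem_curve(sigma = 0.01, seed = 9)
  f <- fit_unfolding(cv, multistart = 1)
  bs <- bootstrap_stderr(f, n = 25, seed = 4)
  expect_true(all(is.finite(bs)))
  for (p in c("Um1", "Um2")) {
    expect_gt(bs[[p]], f$stderr[[p]] / 4)
    expect_lt(bs[[p]], f$stderr[[p]] * 4)
  }
})
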