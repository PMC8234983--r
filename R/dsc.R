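# DSC thermogram processing: baseline subtraction, molar normalization,
# first-derivative transition-temperature location, and two-transition
# van't Hoff deconvolution.

#' DSC thermogram container
#'
#' Temperature vs. heat capacity from a differential scanning calorimetry
#' scan. Temperatures are stored in Kelvin internally; constructors and
#' reports use Celsius. Processing state is tracked by flags so operations
#' cannot be applied out of order (e.g. normalizing before the buffer
#' baseline has been subtracted).
#'
#' @param temperature_C strictly increasing temperatures in Celsius.
#' @param cp heat capacity; raw instrument units before normalization,
#'   kcal mol^-1 K^-1 after.
#' @param scan_rate scan rate, K min^-1 (default 1).
#' @param conc subunit concentration in uM, if known.
#' @param normalized,baseline_subtracted processing flags.
#' @param meta optional named list (construction, generator truth, ...).
#' @return an object of class `dsc_thermogram`.
#' @export
dsc_thermogram <- function(temperature_C, cp, scan_rate = 1, conc = NA_real_,
                           normalized = FALSE, baseline_subtracted = FALSE,
                           meta = list()) {
  .check_finite(temperature_C, "temperature_C"); .check_finite(cp, "cp")
  if (length(temperature_C) != length(cp)) stop("length mismatch", call. = FALSE)
  if (any(diff(temperature_C) <= 0))
    stop("temperature must be strictly increasing", call. = FALSE)
  structure(list(T = celsius_to_kelvin(temperature_C), cp = cp,
                 scan_rate = scan_rate, conc = conc,
                 normalized = normalized,
                 baseline_subtracted = baseline_subtracted, meta = meta),
            class = "dsc_thermogram")
}

#' @export
print.dsc_thermogram <- function(x, ...) {
  cat(sprintf("DSC thermogram: %d points, %.1f-%.1f C%s%s\n",
              length(x$T), kelvin_to_celsius(min(x$T)),
              kelvin_to_celsius(max(x$T)),
              if (x$baseline_subtracted) ", baseline-subtracted" else "",
              if (x$normalized) ", molar-normalized" else ""))
  invisible(x)
}

#' Subtract a buffer baseline scan from a sample thermogram
#'
#' The buffer scan is interpolated linearly onto the sample temperature grid
#' and subtracted pointwise. The temperature ranges must overlap the whole
#' sample grid.
#'
#' @param sample,buffer `dsc_thermogram` objects.
#' @return the sample thermogram with `baseline_subtracted = TRUE`.
#' @export
dsc_subtract_baseline <- function(sample, buffer) {
  stopifnot(inherits(sample, "dsc_thermogram"),
            inherits(buffer, "dsc_thermogram"))
  if (sample$baseline_subtracted)
    stop("baseline already subtracted", call. = FALSE)
  if (min(buffer$T) > min(sample$T) + 1e-9 ||
      max(buffer$T) < max(sample$T) - 1e-9)
    stop("buffer scan does not cover the sample temperature range",
         call. = FALSE)
  b <- stats::approx(buffer$T, buffer$cp, xout = sample$T)$y
  sample$cp <- sample$cp - b
  sample$baseline_subtracted <- TRUE
  sample
}

#' Normalize a thermogram to moles of protein in the cell
#'
#' Divides the (baseline-subtracted) heat capacity by the moles of subunit in
#' the calorimetric cell, turning instrument units into molar excess heat
#' capacity (kcal mol^-1 K^-1 when the raw signal is in kcal K^-1).
#'
#' @param thermogram a baseline-subtracted `dsc_thermogram`.
#' @param conc subunit concentration, uM.
#' @param cell_volume calorimetric cell volume, mL.
#' @return the normalized thermogram.
#' @export
dsc_normalize <- function(thermogram, conc, cell_volume) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  if (!thermogram$baseline_subtracted)
    stop("subtract the buffer baseline before normalizing", call. = FALSE)
  if (thermogram$normalized) stop("already normalized", call. = FALSE)
  if (conc <= 0 || cell_volume <= 0)
    stop("conc and cell_volume must be > 0", call. = FALSE)
  moles <- conc * 1e-6 * cell_volume * 1e-3   # uM * mL -> mol
  thermogram$cp <- thermogram$cp / moles
  thermogram$conc <- conc
  thermogram$normalized <- TRUE
  thermogram
}

#' Transition temperatures from the first derivative of a thermogram
#'
#' Locates the local maxima of the (smoothed) excess heat capacity as the
#' points where its first derivative crosses zero from positive to negative;
#' maxima whose height is below `prominence` times the global maximum are
#' suppressed. Each crossing is refined by quadratic interpolation through the
#' three points around the discrete maximum.
#'
#' @param thermogram a normalized `dsc_thermogram`.
#' @param smooth_window smoothing window for the moving average, in K
#'   (default 1.5, suited to ~0.1 K point spacing at 1 K/min scans).
#' @param prominence fraction of the global peak height below which maxima
#'   are discarded (default 0.05).
#' @return numeric vector of transition temperatures in Celsius, ascending;
#'   empty when no qualifying maximum exists.
#' @export
dsc_find_tm <- function(thermogram, smooth_window = 1.5, prominence = 0.05) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  if (!thermogram$normalized)
    stop("normalize the thermogram before locating transitions", call. = FALSE)
  Tt <- thermogram$T
  dT <- stats::median(diff(Tt))
  k <- max(3L, round(smooth_window / dT))
  cps <- .movavg(thermogram$cp, k)
  n <- length(cps)
  d <- diff(cps) / diff(Tt)
  # + to - zero crossings of the derivative = local maxima of cp
  cross <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cross <- pmax(2L, pmin(n - 1L, cross))
  if (!length(cross)) return(numeric(0))
  # topographic prominence: drop from the peak to the highest of the two
  # valleys separating it from higher ground (noise shoulders on the flank
  # of a larger peak have near-zero prominence even when they are tall)
  prom <- vapply(cross, function(j) {
    h <- cps[j]
    left <- if (j > 1) cps[seq_len(j - 1)] else h
    hi_l <- which(left > h)
    v_l <- if (length(hi_l)) min(left[(max(hi_l)):(j - 1)]) else min(left)
    right <- if (j < n) cps[(j + 1):n] else h
    hi_r <- which(right > h)
    v_r <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(right)
    h - max(v_l, v_r)
  }, 0)
  keep <- cross[prom >= prominence * max(cps)]
  if (!length(keep)) return(numeric(0))
  tms <- vapply(keep, function(j) {
    # quadratic refinement through (j-1, j, j+1)
    y1 <- cps[j - 1]; y2 <- cps[j]; y3 <- cps[j + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
    Tt[j] + max(-1, min(1, off)) * dT
  }, 0)
  sort(kelvin_to_celsius(unique(tms)))
}

#' Two-state van't Hoff excess heat capacity
#'
#' Excess heat capacity of a two-state transition with equal calorimetric and
#' van't Hoff enthalpy:
#' \deqn{C_p^{exc}(T) = \frac{\Delta H_{vH}^2}{R T^2} f (1 - f), \quad
#'  f = \frac{K}{1+K},\; K = e^{-\Delta H_{vH}(1 - T/T_m)/(RT)}.}
#' The curve is single-peaked with maximum marginally below Tm and integrates
#' to dHvH over temperature.
#'
#' @param T absolute temperature(s), K.
#' @param Tm mid-transition temperature, K.
#' @param dHvH van't Hoff enthalpy, kcal mol^-1 (> 0).
#' @return excess heat capacity, kcal mol^-1 K^-1.
#' @export
vanthoff_excess_cp <- function(T, Tm, dHvH) {
  .check_finite(T, "T")
  if (any(T <= 0) || Tm <= 0) stop("temperatures must be > 0", call. = FALSE)
  if (dHvH <= 0) stop("dHvH must be > 0", call. = FALSE)
  u <- -dHvH * (1 - T / Tm) / (.RGAS * T)
  f <- stats::plogis(u)              # K/(1+K) without overflow
  dHvH^2 * f * (1 - f) / (.RGAS * T^2)
}

#' Deconvolve a thermogram into two van't Hoff transitions
#'
#' Least-squares fit of the sum of two independent two-state van't Hoff peaks
#' plus a linear residual baseline,
#' \deqn{C_p(T) = A_1 C_{vH}(T; T_{m1}, \Delta H_1) +
#'               A_2 C_{vH}(T; T_{m2}, \Delta H_2) + c_0 + c_1 T,}
#' initialized from [dsc_find_tm()]. The high-temperature region (commonly
#' distorted by aggregation) is excluded by default: points above the
#' temperature where cp first falls below `cut` times the second peak's
#' height, on its high side, are dropped from the fit.
#'
#' @param thermogram a normalized `dsc_thermogram` with at least one
#'   detectable maximum.
#' @param cut high-side truncation fraction (default 0.25); `NULL` disables
#'   truncation.
#' @param multistart randomized restarts (default 4).
#' @param seed integer seed for restart perturbations.
#' @return an object of class `dsc_fit` with elements `transitions` (data
#'   frame: Tm_C, dHvH, amplitude, degenerate flag), `residuals`, `rss`,
#'   `converged`, `window_C`.
#' @export
dsc_deconvolve <- function(thermogram, cut = 0.25, multistart = 4, seed = 1) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  if (!thermogram$normalized)
    stop("normalize the thermogram before deconvolution", call. = FALSE)
  tm0 <- dsc_find_tm(thermogram)
  if (!length(tm0))
    stop("no detectable transition in thermogram", call. = FALSE)
  if (length(tm0) == 1L) tm0 <- c(tm0, tm0 + 10)
  if (length(tm0) > 2L) {
    # keep the two tallest
    hts <- stats::approx(thermogram$T, thermogram$cp,
                         celsius_to_kelvin(tm0))$y
    tm0 <- sort(tm0[order(hts, decreasing = TRUE)][1:2])
  }
  Tt <- thermogram$T; cp <- thermogram$cp

  # fitting window: drop the aggregation-distorted high-temperature tail
  keep <- rep(TRUE, length(Tt))
  if (!is.null(cut)) {
    T2 <- celsius_to_kelvin(tm0[2])
    h2 <- stats::approx(Tt, .movavg(cp, 5), T2)$y
    hi <- which(Tt > T2 & .movavg(cp, 5) < cut * h2)
    if (length(hi)) keep <- Tt < Tt[min(hi)]
  }
  Tf <- Tt[keep]; cpf <- cp[keep]

  model <- function(p, T) {
    p["A1"] * vanthoff_excess_cp(T, p["Tm1"], p["dH1"]) +
      p["A2"] * vanthoff_excess_cp(T, p["Tm2"], p["dH2"]) +
      p["c0"] + p["c1"] * (T - mean(Tf))
  }
  resid_fn <- function(p) cpf - model(p, Tf)

  p0 <- c(Tm1 = celsius_to_kelvin(tm0[1]), dH1 = 100, A1 = 1,
          Tm2 = celsius_to_kelvin(tm0[2]), dH2 = 100, A2 = 1,
          c0 = min(cpf), c1 = 0)
  lower <- c(min(Tf) - 5, 10, 1e-6, min(Tf) - 5, 10, 1e-6, -Inf, -Inf)
  upper <- c(max(Tt) + 20, 500, 100, max(Tt) + 20, 500, 100, Inf, Inf)

  starts <- .with_seed(seed, {
    s <- list(p0)
    if (multistart > 1)
      for (i in seq_len(multistart - 1)) {
        p <- p0
        p[c("dH1", "dH2")] <- p0[c("dH1", "dH2")] * stats::runif(2, 0.7, 1.5)
        p[c("Tm1", "Tm2")] <- p0[c("Tm1", "Tm2")] + stats::runif(2, -1, 1)
        s[[i + 1]] <- p
      }
    s
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lower), upper),
                         lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(converged = FALSE), class = "dsc_fit"))
  p <- best$fit$par

  # order transitions by Tm; flag a degenerate second component
  ord <- order(p[c("Tm1", "Tm2")])
  areas <- c(p["A1"] * p["dH1"], p["A2"] * p["dH2"])[ord]
  tms <- kelvin_to_celsius(unname(p[c("Tm1", "Tm2")]))[ord]
  dhs <- unname(p[c("dH1", "dH2")])[ord]
  amps <- unname(p[c("A1", "A2")])[ord]
  degen <- areas < 0.05 * sum(areas) | c(FALSE, diff(tms) < 1)

  structure(list(
    transitions = data.frame(Tm_C = tms, dHvH = dhs, amplitude = amps,
                             degenerate = degen),
    baseline = unname(p[c("c0", "c1")]),
    residuals = best$fit$fvec, rss = best$rss,
    window_C = kelvin_to_celsius(range(Tf)),
    converged = best$fit$info %in% 1:4,
    thermogram = thermogram), class = "dsc_fit")
}

#' @export
print.dsc_fit <- function(x, digits = 4, ...) {
  if (!isTRUE(x$converged)) {
    cat("DSC deconvolution did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("Two-transition van't Hoff deconvolution (window %.1f-%.1f C)\n",
              x$window_C[1], x$window_C[2]))
  print(x$transitions, digits = digits, row.names = FALSE)
  cat(sprintf("RSS: %.6g\n", x$rss))
  invisible(x)
}

#' @export
coef.dsc_fit <- function(object, ...) {
  tr <- object$transitions
  stats::setNames(c(tr$Tm_C, tr$dHvH),
                  c("Tm1_C", "Tm2_C", "dHvH1", "dHvH2"))
}

#' @export
plot.dsc_fit <- function(x, ...) {
  tg <- x$thermogram
  TC <- kelvin_to_celsius(tg$T)
  graphics::plot(TC, tg$cp, type = "l", xlab = "temperature (C)",
                 ylab = "excess Cp (kcal/mol/K)", ...)
  tr <- x$transitions
  grid <- tg$T
  for (i in 1:2)
    graphics::lines(TC, tr$amplitude[i] *
                      vanthoff_excess_cp(grid, celsius_to_kelvin(tr$Tm_C[i]),
                                         tr$dHvH[i]),
                    lty = 2, col = "grey50")
  graphics::abline(v = tr$Tm_C, lty = 3)
  invisible(x)
}
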