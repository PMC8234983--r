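# Curve fitting: individual and global (replicate-shared) nonlinear least
# squares of the three-state chemical/thermal unfolding models.
#
# The model is conditionally linear: given the thermodynamic parameters the
# state populations are fixed, and the six baseline coefficients of each curve
# enter linearly. The fit therefore uses variable projection: baselines are
# profiled out by a per-curve linear least-squares solve and the
# Levenberg-Marquardt search runs only over the (shared) thermodynamic
# parameters. This keeps the search space small and the global fit robust.

.movavg <- function(y, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L) return(y)
  n <- length(y)
  out <- stats::filter(y, rep(1 / k, k), sides = 2)
  # fill the ends with shrinking windows
  h <- (k - 1L) %/% 2L
  for (i in seq_len(h)) {
    out[i] <- mean(y[1:(i + h)])
    out[n - i + 1L] <- mean(y[(n - i + 1L - h):n])
  }
  as.numeric(out)
}

.chem_names <- c("Um1", "m1", "Um2", "m2")
.thermal_names <- c("Tm1", "dH1", "Tm2", "dH2", "dCp1", "dCp2")

#' Initial parameter guess for a denaturation curve
#'
#' Locates the two transition midpoints at the two largest-magnitude extrema of
#' a smoothed first derivative of the signal, estimates m-values (or
#' enthalpies) from the derivative peak widths, and seeds the three state
#' baselines from linear fits to the curve edges and the inter-transition
#' plateau. With fewer than two usable derivative extrema (featureless data)
#' the midpoints fall back to the terciles of the x-range and the result is
#' flagged.
#'
#' @param curve a [denaturation_curve()].
#' @param T evaluation temperature (K) for chemical curves.
#' @return a list with elements `thermo` (named numeric vector), `baselines`
#'   (a [signal_baselines()]) and `fallback` (logical).
#' @export
initial_guess <- function(curve, T = 298.15) {
  stopifnot(inherits(curve, "denaturation_curve"))
  mode <- .curve_mode(curve)
  x <- curve$x; y <- curve$y; n <- length(x)
  xr <- diff(range(x))
  ys <- .movavg(y, round(n / 8))
  d <- diff(ys) / diff(x)
  xm <- (x[-1] + x[-n]) / 2
  ds <- .movavg(d, 3)

  # interior local extrema of the smoothed derivative; data indistinguishable
  # from a straight line carry no transition signal at all
  lin_res <- stats::lm.fit(cbind(1, x), y)$residuals
  featureless <- max(abs(lin_res)) <= 1e-8 * max(diff(range(y)), 1e-300)
  idx <- which(diff(sign(diff(ds))) != 0) + 1L
  idx <- idx[abs(ds[idx]) > 0.05 * max(abs(ds))]
  if (featureless) idx <- integer(0)
  fallback <- FALSE
  if (length(idx) >= 2L) {
    top <- idx[order(abs(ds[idx]), decreasing = TRUE)]
    # keep the two largest that are decently separated
    pick <- top[1]
    for (i in top[-1]) {
      if (abs(xm[i] - xm[pick[1]]) > 0.15 * xr) { pick <- c(pick, i); break }
    }
    if (length(pick) == 2L) {
      pick <- pick[order(xm[pick])]
      mids <- xm[pick]
      widths <- vapply(pick, function(i) {
        h <- abs(ds[i]) / 2
        l <- i; while (l > 1 && abs(ds[l]) > h) l <- l - 1L
        r <- i; while (r < length(ds) && abs(ds[r]) > h) r <- r + 1L
        max(xm[r] - xm[l], 2 * mean(diff(x)))
      }, 0)
    } else fallback <- TRUE
  } else fallback <- TRUE
  if (fallback) {
    mids <- min(x) + c(1, 2) / 3 * xr
    widths <- rep(xr / 6, 2)
  }

  # steepness guesses from derivative FWHM: for a two-state transition the
  # population-derivative FWHM is ~3.53 RT/m (chemical) or ~3.53 R Tm^2/dH
  if (mode == "chemical") {
    m12 <- pmin(pmax(3.53 * .RGAS * T / widths, 0.3), 10)
    thermo <- c(Um1 = mids[1], m1 = m12[1], Um2 = mids[2], m2 = m12[2])
  } else {
    dh <- pmin(pmax(3.53 * .RGAS * mids^2 / widths, 30), 300)
    thermo <- c(Tm1 = mids[1], dH1 = dh[1], Tm2 = mids[2], dH2 = dh[2],
                dCp1 = 0, dCp2 = 0)
  }

  # edge baselines from linear fits to the first/last 15% of points
  k <- max(2L, ceiling(0.15 * n))
  lin <- function(xi, yi) {
    if (length(xi) < 2L || diff(range(xi)) == 0) return(c(mean(yi), 0))
    cf <- stats::coef(stats::lm.fit(cbind(1, xi), yi))
    c(cf[1], cf[2])
  }
  bn <- lin(x[1:k], y[1:k])
  bu <- lin(x[(n - k + 1):n], y[(n - k + 1):n])
  # intermediate baseline from the central half of the inter-midpoint plateau
  sel <- which(x > mids[1] + 0.25 * (mids[2] - mids[1]) &
               x < mids[2] - 0.25 * (mids[2] - mids[1]))
  bi <- if (length(sel) >= 3L) lin(x[sel], ys[sel])
        else c(mean(ys[x >= mids[1] & x <= mids[2]]), 0)
  if (!all(is.finite(bi))) bi <- c(mean(ys), 0)

  list(thermo = thermo,
       baselines = signal_baselines(bn[1], bn[2], bi[1], bi[2], bu[1], bu[2],
                                    x_kind = mode),
       fallback = fallback)
}

.default_bounds <- function(mode, curves, float_dcp = FALSE) {
  xs <- unlist(lapply(curves, `[[`, "x"))
  xr <- diff(range(xs))
  lo_x <- min(xs) - 0.1 * xr; hi_x <- max(xs) + 0.1 * xr
  if (mode == "chemical") {
    list(Um1 = c(max(lo_x, 1e-6), hi_x), m1 = c(1e-3, 20),
         Um2 = c(max(lo_x, 1e-6), hi_x), m2 = c(1e-3, 20))
  } else {
    b <- list(Tm1 = c(lo_x, hi_x), dH1 = c(1e-2, 500),
              Tm2 = c(lo_x, hi_x), dH2 = c(1e-2, 500),
              dCp1 = c(0, 10), dCp2 = c(0, 10))
    b
  }
}

.state_fractions_at <- function(theta, x, mode, T) {
  if (mode == "chemical") {
    g1 <- theta[["m1"]] * (theta[["Um1"]] - x)
    g2 <- theta[["m2"]] * (theta[["Um2"]] - x)
    species_fractions(g1, g2, T)
  } else {
    g1 <- thermal_free_energy(x, theta[["Tm1"]], theta[["dH1"]], theta[["dCp1"]])
    g2 <- thermal_free_energy(x, theta[["Tm2"]], theta[["dH2"]], theta[["dCp2"]])
    species_fractions(g1, g2, x)
  }
}

# profile out the 6 linear baseline coefficients of one curve; returns
# residuals and coefficients (rank-deficient columns dropped to 0)
.profile_curve <- function(theta, curve, mode, T) {
  x <- curve$x; y <- curve$y
  f <- .state_fractions_at(theta, x, mode, T)
  A <- cbind(f[, 1], f[, 1] * x, f[, 2], f[, 2] * x, f[, 3], f[, 3] * x)
  sol <- stats::lm.fit(A, y)
  b <- unname(sol$coefficients)
  b[is.na(b)] <- 0
  list(resid = y - drop(A %*% b), coef = b)
}

.vp_residuals <- function(theta, curves, mode, T) {
  unlist(lapply(curves, function(cv) .profile_curve(theta, cv, mode, T)$resid),
         use.names = FALSE)
}

.num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Fit the three-state unfolding model to one or several curves
#'
#' Nonlinear least-squares fit of the chemical (LEM) or thermal
#' (Gibbs-Helmholtz) three-state model. With several curves the fit is global:
#' one shared thermodynamic parameter vector jointly minimizes the pooled
#' residuals while every curve keeps its own six baseline coefficients (the
#' standard replicate global-fit convention). With a single curve this reduces
#' exactly to an individual fit.
#'
#' Baselines are profiled out by linear least squares at every objective
#' evaluation (variable projection), so the nonlinear search runs only over
#' the thermodynamic parameters, with box bounds keeping it in the physical
#' basin (midpoints within the observed x-range +/- 10%, m-values in (0, 20]
#' kcal mol^-1 M^-1, enthalpies in (0, 500] kcal mol^-1). The search is
#' restarted `multistart` times from seeded +/-20% perturbations of the
#' data-driven initial guess and the lowest-RSS solution is returned.
#' Standard errors come from the scaled inverse Gauss-Newton normal matrix of
#' the profiled residuals at the optimum.
#'
#' Thermal fits keep both heat-capacity changes fixed at 0 by default (they
#' are rarely determined well enough by a fluorescence curve to report); pass
#' `float_dcp = TRUE` to release them.
#'
#' @param curves a [denaturation_curve()] or a list of them (all same mode).
#' @param fixed named list of thermodynamic parameters to hold fixed.
#' @param bounds named list overriding default box bounds, each entry
#'   `c(lower, upper)`.
#' @param multistart number of randomized restarts (>= 1), default 8.
#' @param seed integer seed for the restart perturbations.
#' @param float_dcp logical; release dCp1/dCp2 in thermal fits.
#' @param T evaluation temperature (K) for chemical fits, default 298.15.
#' @return an object of class `unfolding_fit`; see [coef.unfolding_fit()],
#'   [summary.unfolding_fit()], [predict.unfolding_fit()], [populations()].
#' @examples
#' truth <- chem_params(2.70, 1.91, 5.48, 2.12)
#' bl <- signal_baselines(100, 1, 190, 0, 120, -1.5)
#' cv <- simulate_chem_curve(truth, bl, noise = noise_model(0))
#' fit <- fit_unfolding(cv, multistart = 1)
#' coef(fit)
#' @export
fit_unfolding <- function(curves, fixed = NULL, bounds = NULL, multistart = 8,
                          seed = 1, float_dcp = FALSE, T = 298.15) {
  curves <- .as_curve_list(curves)
  mode <- .curve_mode(curves[[1]])
  if (multistart < 1) stop("multistart must be >= 1", call. = FALSE)

  pnames <- if (mode == "chemical") .chem_names else .thermal_names
  fixed <- as.list(fixed)
  if (length(fixed) && !all(names(fixed) %in% pnames))
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), pnames), collapse = ", "), call. = FALSE)
  if (mode == "thermal" && !float_dcp) {
    if (is.null(fixed$dCp1)) fixed$dCp1 <- 0
    if (is.null(fixed$dCp2)) fixed$dCp2 <- 0
  }
  free <- setdiff(pnames, names(fixed))

  bnd <- .default_bounds(mode, curves)
  for (nm in names(bounds)) bnd[[nm]] <- bounds[[nm]]
  for (nm in names(fixed)) {
    v <- fixed[[nm]]
    if (v < bnd[[nm]][1] - 1e-12 || v > bnd[[nm]][2] + 1e-12)
      stop("fixed value for ", nm, " outside its bounds", call. = FALSE)
  }

  # data-driven start: per-curve guesses averaged over curves
  guesses <- lapply(curves, initial_guess, T = T)
  g0 <- rowMeans(vapply(guesses, function(g) g$thermo[pnames], numeric(length(pnames))))
  names(g0) <- pnames
  g0[names(fixed)] <- unlist(fixed)
  fallback <- any(vapply(guesses, `[[`, TRUE, "fallback"))

  full_theta <- function(par) {
    th <- g0
    th[free] <- par
    th
  }
  objective <- function(par) .vp_residuals(full_theta(par), curves, mode, T)

  lower <- vapply(bnd[free], `[`, 0, 1)
  upper <- vapply(bnd[free], `[`, 0, 2)
  clamp <- function(p) pmin(pmax(p, lower), upper)

  starts <- .with_seed(seed, {
    s <- list(g0[free])
    if (multistart > 1)
      for (i in seq_len(multistart - 1))
        s[[i + 1]] <- clamp(g0[free] * stats::runif(length(free), 0.8, 1.2))
    s
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = clamp(st), lower = lower, upper = upper,
                         fn = objective,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(mode = mode, converged = FALSE, coef = g0,
                          stderr = stats::setNames(rep(NA_real_, length(pnames)), pnames),
                          rss = NA_real_, n_curves = length(curves),
                          curves = curves, guess_fallback = fallback),
                     class = "unfolding_fit"))
  }
  fit <- best$fit
  theta <- full_theta(stats::setNames(fit$par, free))

  prof <- lapply(curves, function(cv) .profile_curve(theta, cv, mode, T))
  baselines <- lapply(prof, function(p)
    signal_baselines(p$coef[1], p$coef[2], p$coef[3], p$coef[4],
                     p$coef[5], p$coef[6], x_kind = mode))
  residuals <- lapply(prof, `[[`, "resid")
  nobs <- sum(lengths(residuals))
  npar <- length(free) + 6L * length(curves)
  rss <- sum(unlist(residuals)^2)
  dof <- max(nobs - npar, 1L)
  sigma2 <- rss / dof

  # covariance of the nonlinear parameters from the profiled residual Jacobian
  J <- .num_jacobian(objective, fit$par)
  JtJ <- crossprod(J)
  sv <- svd(JtJ)
  pos <- sv$d > max(sv$d) * 1e-12
  cov <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos]) * sigma2
  se_free <- sqrt(pmax(diag(cov), 0))
  stderr <- stats::setNames(rep(NA_real_, length(pnames)), pnames)
  stderr[free] <- se_free

  thermo <- if (mode == "chemical")
    chem_params(theta[["Um1"]], theta[["m1"]], theta[["Um2"]], theta[["m2"]])
  else
    thermal_params(theta[["Tm1"]], theta[["dH1"]],
                   max(theta[["Tm2"]], theta[["Tm1"]]), theta[["dH2"]],
                   theta[["dCp1"]], theta[["dCp2"]])

  structure(list(
    mode = mode, thermo = thermo, coef = theta, stderr = stderr,
    free = free, fixed = fixed, baselines = baselines,
    residuals = residuals, rss = rss, sigma2 = sigma2, nobs = nobs,
    n_curves = length(curves), curves = curves, T = T,
    converged = fit$info %in% 1:4, info = fit$info,
    guess_fallback = fallback, multistart = multistart, seed = seed,
    vcov_free = cov), class = "unfolding_fit")
}

#' @export
coef.unfolding_fit <- function(object, ...) object$coef

#' @export
vcov.unfolding_fit <- function(object, ...) {
  v <- object$vcov_free
  dimnames(v) <- list(object$free, object$free)
  v
}

#' @export
residuals.unfolding_fit <- function(object, ...)
  unlist(object$residuals, use.names = FALSE)

#' @export
fitted.unfolding_fit <- function(object, ...) {
  unlist(lapply(seq_len(object$n_curves), function(i)
    object$curves[[i]]$y - object$residuals[[i]]), use.names = FALSE)
}

#' @export
deviance.unfolding_fit <- function(object, ...) object$rss

#' @export
print.unfolding_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Three-state %s unfolding fit: %d curve(s), %d observations\n",
              x$mode, x$n_curves, if (is.null(x$nobs)) NA else x$nobs))
  if (!x$converged) {
    cat("  ** fit did not converge **\n")
    return(invisible(x))
  }
  s <- summary(x)
  print(s$parameters, digits = digits, row.names = FALSE)
  cat(sprintf("Residual sum of squares: %.6g\n", x$rss))
  invisible(x)
}

#' Summarize a three-state unfolding fit
#'
#' Tabulates the fitted thermodynamic parameters with their standard errors in
#' report units: midpoints in M (chemical) or degrees Celsius (thermal),
#' m-values in kcal mol^-1 M^-1, enthalpies in kcal mol^-1.
#'
#' @param object an `unfolding_fit`.
#' @param ... unused.
#' @return a list with a `parameters` data frame, `rss`, `converged`.
#' @export
summary.unfolding_fit <- function(object, ...) {
  cf <- object$coef; se <- object$stderr
  if (object$mode == "chemical") {
    tab <- data.frame(
      parameter = c("Um1", "m1", "Um2", "m2"),
      value = unname(cf[.chem_names]),
      stderr = unname(se[.chem_names]),
      unit = c("M", "kcal/mol/M", "M", "kcal/mol/M"))
  } else {
    nm <- intersect(.thermal_names, names(cf))
    val <- unname(cf[nm]); s <- unname(se[nm])
    cel <- nm %in% c("Tm1", "Tm2")
    val[cel] <- kelvin_to_celsius(val[cel])
    tab <- data.frame(parameter = nm, value = val, stderr = s,
                      unit = ifelse(cel, "C",
                             ifelse(grepl("dH", nm), "kcal/mol", "kcal/mol/K")))
  }
  out <- list(parameters = tab, rss = object$rss, converged = object$converged,
              n_curves = object$n_curves)
  class(out) <- "summary.unfolding_fit"
  out
}

#' @export
print.summary.unfolding_fit <- function(x, digits = 4, ...) {
  print(x$parameters, digits = digits, row.names = FALSE)
  cat(sprintf("RSS %.6g over %d curve(s); converged: %s\n",
              x$rss, x$n_curves, x$converged))
  invisible(x)
}

#' Predict signal or state populations from a fitted unfolding model
#'
#' @param object an `unfolding_fit`.
#' @param newdata x values (M or K); defaults to the x grid of `curve`.
#' @param type `"signal"` (uses the per-curve baselines) or `"fractions"`.
#' @param curve index of the curve whose baselines to use for signals.
#' @param ... unused.
#' @return numeric vector of signals, or a matrix of fractions.
#' @export
predict.unfolding_fit <- function(object, newdata = NULL,
                                  type = c("signal", "fractions"),
                                  curve = 1L, ...) {
  type <- match.arg(type)
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  x <- if (is.null(newdata)) object$curves[[curve]]$x else newdata
  if (type == "fractions")
    return(.state_fractions_at(object$coef, x, object$mode, object$T))
  f <- .state_fractions_at(object$coef, x, object$mode, object$T)
  rowSums(f * .baseline_matrix(object$baselines[[curve]], x))
}

#' State populations along a grid
#'
#' Native, intermediate and unfolded molar fractions predicted by a converged
#' fit on an arbitrary grid of denaturant concentrations or temperatures. This
#' is the computation behind statements like "at 5.4 M urea the protein is
#' mostly in the intermediate conformation".
#'
#' @param fit a converged `unfolding_fit`.
#' @param grid numeric vector of x values (M or K).
#' @return matrix with columns `fN`, `fI`, `fU`; rows sum to 1.
#' @export
populations <- function(fit, grid) {
  stopifnot(inherits(fit, "unfolding_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  .state_fractions_at(fit$coef, grid, fit$mode, fit$T)
}

#' @export
plot.unfolding_fit <- function(x, which = seq_len(x$n_curves), ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  xlab <- if (x$mode == "chemical") "[urea] (M)" else "temperature (C)"
  toX <- if (x$mode == "thermal") kelvin_to_celsius else identity
  allx <- unlist(lapply(x$curves, `[[`, "x"))
  ally <- unlist(lapply(x$curves, `[[`, "y"))
  graphics::plot(toX(allx), ally, col = "grey40", pch = 16, cex = 0.5,
                 xlab = xlab, ylab = "signal (a.u.)", ...)
  grid <- seq(min(allx), max(allx), length.out = 200)
  for (i in which)
    graphics::lines(toX(grid), predict(x, grid, curve = i), col = i + 1)
  f <- populations(x, grid)
  graphics::matplot(toX(grid), f, type = "l", lty = 1,
                    col = c("black", "orange", "red"),
                    xlab = xlab, ylab = "molar fraction")
  graphics::legend("right", c("N", "I", "U"), lty = 1,
                   col = c("black", "orange", "red"), bty = "n")
  invisible(x)
}

#' Residual-bootstrap standard errors for an unfolding fit
#'
#' Refits the model to `n` pseudo-datasets built by adding resampled residuals
#' to the fitted values, and reports the standard deviation of each free
#' thermodynamic parameter across refits. A complement to the
#' curvature-based errors when those are doubted.
#'
#' @param fit a converged `unfolding_fit`.
#' @param n number of bootstrap replicates, default 200.
#' @param seed integer seed.
#' @return named numeric vector of bootstrap standard errors.
#' @export
bootstrap_stderr <- function(fit, n = 200, seed = 1) {
  stopifnot(inherits(fit, "unfolding_fit"), fit$converged)
  res <- unlist(fit$residuals, use.names = FALSE)
  lens <- lengths(fit$residuals)
  draws <- .with_seed(seed, {
    out <- matrix(NA_real_, n, length(fit$free))
    for (b in seq_len(n)) {
      rs <- sample(res, length(res), replace = TRUE)
      cvs <- vector("list", length(fit$curves))
      off <- 0L
      for (i in seq_along(fit$curves)) {
        cv <- fit$curves[[i]]
        yhat <- cv$y - fit$residuals[[i]]
        cvs[[i]] <- denaturation_curve(cv$x, yhat + rs[(off + 1):(off + lens[i])],
                                       mode = fit$mode)
        off <- off + lens[i]
      }
      bf <- tryCatch(fit_unfolding(cvs, fixed = fit$fixed, multistart = 1,
                                   seed = seed + b, T = fit$T),
                     error = function(e) NULL)
      if (!is.null(bf) && bf$converged) out[b, ] <- bf$coef[fit$free]
    }
    out
  })
  stats::setNames(apply(draws, 2, stats::sd, na.rm = TRUE), fit$free)
}
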