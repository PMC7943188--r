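#' Fit an equilibrium gating model to a normalized curve
#'
#' The central fitting routine of the package. Fits one of the three
#' closed-form gating models to a cohort-mean curve by (unit-weight)
#' nonlinear least squares, the procedure used for published G-V / Q-V /
#' Inac-V tables:
#'
#' * `"two_state"`: the Boltzmann `1 / (1 + exp(z (V1/2 - Vm) F/RT))` with
#'   parameters `z`, `v_half` (used for G-V curves and for shallow Q-V
#'   curves). A free scale multiplies the curve: empirical per-cell
#'   max-normalization pins the plateau of a measured curve only up to the
#'   noise in each cell's maximum, and forcing the asymptote to exactly 1
#'   biases `z` and `v_half`; the scale absorbs that artifact and converges
#'   to 1 on noiseless data. Pass `fix_scale = 1` for the strict
#'   fixed-asymptote form;
#' * `"three_state"`: the sequential charge curve of [qv_three_state()]
#'   with parameters `z0`, `v0`, `z1`, `v1` and scale `n`. For normalized
#'   data `n` is fitted (a curve normalized to 1 implies
#'   `n = 1/(z0 + z1)`, which is also the initial value); pass
#'   `fix_n` to pin it. The scale role is played by `n`.
#' * `"inac"`: the descending availability curve of [inac_curve()] with
#'   parameters `z_inac`, `v_half_inac` and asymptotes `a1 >= 0`, `a2`.
#'
#' Initialization follows the usual heuristics: the midpoint voltage from
#' the half-maximum crossing by linear interpolation, the valence from the
#' 25-75 percent slope (`z = 2 ln(3) (RT/F) / (V75 - V25)`), and for the
#' three-state model the curve is split at its steepest point to seed the
#' two transitions. Three multistarts with scaled initial valences are run
#' and the lowest sum of squared residuals wins (ties: fewest free
#' parameters, then first found). Bounds: valences in (0, 20], midpoints
#' within the grid extended by 50 mV.
#'
#' Parameter standard errors come from the Jacobian-based covariance at the
#' optimum; they are fit errors, reported separately from the cohort SEM
#' stored on the curve.
#'
#' @param curve a [build_curve()] / [as_normalized_curve()] object, or a
#'   data.frame with columns `voltage_mV` and `value`.
#' @param model `"two_state"`, `"three_state"` or `"inac"`.
#' @param k a [gating_constants()] object.
#' @param fix_n fix the three-state scale to this value instead of fitting
#'   it (`NULL` = fit).
#' @param fix_scale fix the two-state amplitude (e.g. to 1) instead of
#'   fitting it; ignored by the other models.
#' @param start optional named list overriding the automatic starts.
#' @return An object of class `gating_fit` with methods `print()`,
#'   `summary()`, `coef()`, `vcov()`, `predict()`, `fitted()`,
#'   `residuals()`, `plot()` and `simulate()`.
#' @examples
#' k <- gating_constants()
#' v <- seq(-120, 40, 5)
#' cv <- as_normalized_curve(v, gv_two_state(two_state_params(1.6, -52.5), v, k), "GV")
#' coef(fit_gv(cv, k = k))
#' @export
gating_fit <- function(curve, model = c("two_state", "three_state", "inac"),
                       k = gating_constants(), fix_n = NULL,
                       fix_scale = NULL, start = NULL) {
  model <- match.arg(model)
  k <- as_gating_constants(k)
  if (is.data.frame(curve)) {
    stopifnot(all(c("voltage_mV", "value") %in% names(curve)))
    curve <- as_normalized_curve(curve$voltage_mV, curve$value, kind = "QV")
  }
  stopifnot(inherits(curve, "normalized_curve"))
  v <- as.numeric(curve$voltage_mV)
  y <- unname(as.numeric(curve$mean))
  ok <- is.finite(y)
  v <- v[ok]; y <- y[ok]
  if (length(unique(v)) < switch(model, two_state = 3L, inac = 4L,
                                 three_state = 6L)) {
    stop(sprintf("under-determined: %s model needs more distinct voltages", model),
         call. = FALSE)
  }
  if (diff(range(y)) < 1e-3) {
    stop("curve is flat: no voltage dependence to fit", call. = FALSE)
  }

  kT <- k$kT_mV
  incr <- y[length(y)] >= y[1]
  yn <- (y - min(y)) / diff(range(y))
  if (!incr) yn <- 1 - yn
  cross <- function(level) {
    i <- which(yn >= level)[1]
    if (is.na(i) || i == 1L) return(v[1])
    v[i - 1] + (level - yn[i - 1]) / (yn[i] - yn[i - 1]) * (v[i] - v[i - 1])
  }
  v50 <- cross(0.5)
  dv <- max(cross(0.75) - cross(0.25), 1)
  z0g <- min(max(2 * log(3) * kT / dv, 0.05), 19)
  lo_v <- min(v) - 50; hi_v <- max(v) + 50

  fits <- list()
  for (sc in c(1, 0.5, 2)) {
    st <- switch(model,
      two_state = list(z = z0g * sc, v_half = v50,
                       scale = if (is.null(fix_scale)) 1 else fix_scale),
      inac = list(z = z0g * sc, v_half = v50, a1 = max(min(y), 0),
                  a2 = max(y)),
      three_state = {
        z_each <- min(max(z0g * sc, 0.1), 15)
        list(z0 = z_each, v0 = cross(0.3), z1 = min(2 * z_each, 15),
             v1 = cross(0.7),
             n = if (is.null(fix_n)) 1 / (3 * z_each) else fix_n)
      })
    if (!is.null(start)) st[names(start)] <- start
    f <- try_fit_model(model, v, y, st, kT, lo_v, hi_v, fix_n, fix_scale)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("model fit failed to converge", call. = FALSE)
  ssrs <- vapply(fits, function(f) f$ssr, numeric(1))
  best <- fits[[which.min(ssrs)]]

  structure(
    list(model = model, coefficients = best$coef, se = best$se,
         vcov = best$vcov, ssr = best$ssr, sigma = best$sigma,
         fitted.values = best$fitted, residuals = y - best$fitted,
         data = list(voltage_mV = v, value = y,
                     sem = curve$sem[ok], n_cells = curve$n_cells,
                     kind = curve$kind),
         constants = k, converged = best$converged,
         n_obs = length(y)),
    class = "gating_fit"
  )
}

model_formula_fun <- function(model, kT) {
  switch(model,
    two_state = function(p, v) {
      p["scale"] / (1 + clip_exp(p["z"] * (p["v_half"] - v) / kT))
    },
    inac = function(p, v) {
      p["a2"] + (p["a1"] - p["a2"]) /
        (1 + clip_exp(p["z"] * (p["v_half"] - v) / kT))
    },
    three_state = function(p, v) {
      e1 <- clip_exp(p["z1"] * (p["v1"] - v) / kT)
      e0 <- clip_exp(p["z0"] * (p["v0"] - v) / kT)
      p["n"] * (p["z1"] + p["z0"] * (1 + e1)) / ((1 + e1) * (1 + e0))
    })
}

model_bounds <- function(model, lo_v, hi_v, fix_n) {
  switch(model,
    two_state = list(lower = c(z = 1e-3, v_half = lo_v, scale = 0.3),
                     upper = c(z = 20, v_half = hi_v, scale = 1.7)),
    inac = list(lower = c(z = 1e-3, v_half = lo_v, a1 = 0, a2 = 0),
                upper = c(z = 20, v_half = hi_v, a1 = 2, a2 = 2)),
    three_state = list(lower = c(z0 = 1e-3, v0 = lo_v, z1 = 1e-3, v1 = lo_v,
                                 n = 1e-6),
                       upper = c(z0 = 20, v0 = hi_v, z1 = 20, v1 = hi_v,
                                 n = 100)))
}

try_fit_model <- function(model, v, y, st, kT, lo_v, hi_v, fix_n,
                          fix_scale = NULL) {
  fn <- model_formula_fun(model, kT)
  b <- model_bounds(model, lo_v, hi_v, fix_n)
  par0 <- unlist(st)
  fixed <- NULL
  if (model == "three_state" && !is.null(fix_n)) {
    fixed <- c(n = fix_n)
  } else if (model == "two_state" && !is.null(fix_scale)) {
    fixed <- c(scale = fix_scale)
  }
  if (!is.null(fixed)) {
    par0 <- par0[setdiff(names(par0), names(fixed))]
    b$lower <- b$lower[setdiff(names(b$lower), names(fixed))]
    b$upper <- b$upper[setdiff(names(b$upper), names(fixed))]
  }
  par0 <- pmin(pmax(par0, b$lower[names(par0)]), b$upper[names(par0)])
  resid_fun <- function(p) {
    pp <- c(p, fixed)
    y - fn(pp, v)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fun,
                       lower = b$lower[names(par0)],
                       upper = b$upper[names(par0)],
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  ssr <- sum(fit$fvec^2)
  npar <- length(p)
  dof <- max(length(y) - npar, 1)
  sigma2 <- ssr / dof
  # Jacobian-based covariance at the optimum
  J <- numeric_jacobian(function(p) fn(c(p, fixed), v), p)
  vc <- tryCatch(sigma2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, npar, npar,
                                            dimnames = list(names(p), names(p))))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(p)
  coefs <- c(p, fixed)
  se_all <- c(se, if (!is.null(fixed)) stats::setNames(rep(0, length(fixed)), names(fixed)))
  list(coef = coefs, se = se_all[names(coefs)], vcov = vc, ssr = ssr,
       sigma = sqrt(sigma2), fitted = fn(coefs, v),
       converged = fit$info %in% 1:4)
}

numeric_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p), dimnames = list(NULL, names(p)))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

#' @rdname gating_fit
#' @export
fit_gv <- function(curve, k = gating_constants(), fix_scale = NULL,
                   start = NULL) {
  gating_fit(curve, "two_state", k = k, fix_scale = fix_scale, start = start)
}

#' @rdname gating_fit
#' @param model_qv `"two_state"` or `"three_state"` for Q-V fitting.
#' @export
fit_qv <- function(curve, model_qv = c("three_state", "two_state"),
                   k = gating_constants(), fix_n = NULL, fix_scale = NULL,
                   start = NULL) {
  model_qv <- match.arg(model_qv)
  gating_fit(curve, model_qv, k = k, fix_n = fix_n, fix_scale = fix_scale,
             start = start)
}

#' @rdname gating_fit
#' @export
fit_inacv <- function(curve, k = gating_constants(), start = NULL) {
  gating_fit(curve, "inac", k = k, start = start)
}

#' Choose between two-state and three-state Q-V models
#'
#' Fits both models and selects by AIC computed from the least-squares
#' deviance (`n log(SSR/n) + 2 p`), which penalizes the three extra
#' parameters of the sequential model; a configuration override always
#' wins. If the three-state fit is infeasible (too few voltages) the
#' two-state model is selected.
#'
#' @param curve a normalized Q-V curve.
#' @param override `NULL`, `"two_state"` or `"three_state"`.
#' @param k a [gating_constants()] object.
#' @return A list with `model` (the selected id), `fit` (the selected
#'   [gating_fit()]), and `aic` (named vector of both criteria, where
#'   available).
#' @export
model_select_qv <- function(curve, override = NULL, k = gating_constants()) {
  if (!is.null(override)) {
    override <- match.arg(override, c("two_state", "three_state"))
    f <- gating_fit(curve, override, k = k)
    return(list(model = override, fit = f, aic = c()))
  }
  f2 <- gating_fit(curve, "two_state", k = k)
  f3 <- tryCatch(gating_fit(curve, "three_state", k = k), error = function(e) NULL)
  aic_of <- function(f) {
    n <- f$n_obs
    n * log(f$ssr / n) + 2 * length(f$coefficients)
  }
  if (is.null(f3)) {
    return(list(model = "two_state", fit = f2, aic = c(two_state = aic_of(f2))))
  }
  aic <- c(two_state = aic_of(f2), three_state = aic_of(f3))
  if (aic["three_state"] < aic["two_state"]) {
    list(model = "three_state", fit = f3, aic = aic)
  } else {
    list(model = "two_state", fit = f2, aic = aic)
  }
}

#' @export
print.gating_fit <- function(x, ...) {
  cat(sprintf("<gating_fit: %s model, %d points, SSR = %.3g>\n",
              x$model, x$n_obs, x$ssr))
  co <- x$coefficients
  se <- x$se
  for (nm in names(co)) {
    cat(sprintf("  %-12s %10.4g +/- %.3g\n", nm, co[nm],
                if (is.na(se[nm])) NA else se[nm]))
  }
  invisible(x)
}

#' @export
summary.gating_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se[names(object$coefficients)])
  out <- list(model = object$model, coefficients = tab, ssr = object$ssr,
              sigma = object$sigma, n_obs = object$n_obs,
              n_cells = object$data$n_cells, converged = object$converged)
  class(out) <- "summary.gating_fit"
  out
}

#' @export
print.summary.gating_fit <- function(x, ...) {
  cat(sprintf("Gating model fit (%s), %d voltages, cohort of %d cell(s)\n",
              x$model, x$n_obs, x$n_cells))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("Residual sigma %.3g on fit, SSR %.4g, converged: %s\n",
              x$sigma, x$ssr, x$converged))
  invisible(x)
}

#' @export
coef.gating_fit <- function(object, ...) object$coefficients

#' @export
vcov.gating_fit <- function(object, ...) object$vcov

#' @export
fitted.gating_fit <- function(object, ...) object$fitted.values

#' @export
residuals.gating_fit <- function(object, ...) object$residuals

#' @export
predict.gating_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$voltage_mV
       else if (is.data.frame(newdata)) newdata$voltage_mV
       else newdata
  fn <- model_formula_fun(object$model, object$constants$kT_mV)
  unname(fn(object$coefficients, v))
}

#' @export
plot.gating_fit <- function(x, n_grid = 200, ...) {
  d <- x$data
  graphics::plot(d$voltage_mV, d$value, pch = 16, xlab = "Vm (mV)",
                 ylab = d$kind, ...)
  if (any(d$sem > 0)) {
    graphics::arrows(d$voltage_mV, d$value - d$sem, d$voltage_mV,
                     d$value + d$sem, angle = 90, code = 3, length = 0.02)
  }
  vg <- seq(min(d$voltage_mV), max(d$voltage_mV), length.out = n_grid)
  graphics::lines(vg, predict(x, vg), col = 2)
  invisible(x)
}

#' @export
simulate.gating_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma),
            simplify = "matrix")
}

#' Extract fitted parameters as a model parameter object
#'
#' Converts a `gating_fit` back into the matching parameter container
#' ([two_state_params()], [three_state_params()] or [inac_params()]), with
#' standard errors attached, so it can be fed to the forward models or the
#' energy calculations.
#'
#' @param fit a [gating_fit()].
#' @return A parameter object of the matching class.
#' @export
fit_params <- function(fit) {
  stopifnot(inherits(fit, "gating_fit"))
  co <- fit$coefficients; se <- fit$se
  switch(fit$model,
    two_state = two_state_params(co["z"], co["v_half"], se["z"], se["v_half"]),
    three_state = three_state_params(co["z0"], co["v0"], co["z1"], co["v1"],
                                     n = co["n"], se_z0 = se["z0"],
                                     se_v0 = se["v0"], se_z1 = se["z1"],
                                     se_v1 = se["v1"], se_n = se["n"]),
    inac = inac_params(co["z"], co["v_half"], co["a1"], co["a2"],
                       se["z"], se["v_half"], se["a1"], se["a2"]))
}

#' Serialize a fit result to JSON
#'
#' @param fit a [gating_fit()].
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "gating_fit"))
  obj <- list(model = fit$model,
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              vcov = fit$vcov, ssr = fit$ssr, sigma = fit$sigma,
              n_obs = fit$n_obs, converged = fit$converged,
              data = fit$data)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
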