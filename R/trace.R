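#' Peak current within a window
#'
#' Finds the extremum of a (optionally leak-subtracted) current trace in a
#' time window. A short boxcar smooth is applied before the extremum search
#' so single noise samples do not set the peak; the returned value is the
#' smoothed current at the extremum.
#'
#' @param time_ms,current_uA the trace.
#' @param window `c(t0, t1)` in ms; the search interval.
#' @param polarity `"auto"` (largest absolute excursion, signed value
#'   returned), `"positive"` or `"negative"`.
#' @param smooth_n boxcar width in samples (odd; 1 disables smoothing).
#' @param leak optional list `list(g, i0)`: a linear leak `g * Vm + i0`
#'   subtracted before the search (requires `voltage_mV`).
#' @param voltage_mV command voltage trace (only needed with `leak`).
#' @return A list with `peak_uA`, `t_peak_ms` and `index`.
#' @export
peak_current <- function(time_ms, current_uA, window,
                         polarity = c("auto", "positive", "negative"),
                         smooth_n = 5, leak = NULL, voltage_mV = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(time_ms) == length(current_uA), length(window) == 2L,
            window[2] > window[1])
  idx <- which(time_ms >= window[1] & time_ms <= window[2])
  if (length(idx) == 0L) stop("empty peak-search window", call. = FALSE)
  y <- current_uA
  if (!is.null(leak)) {
    if (is.null(voltage_mV)) stop("leak subtraction needs `voltage_mV`", call. = FALSE)
    y <- y - (leak$g * voltage_mV + (leak$i0 %||% 0))
  }
  yw <- y[idx]
  if (smooth_n > 1 && length(yw) > smooth_n) {
    # smooth inside the window only, so adjacent protocol segments cannot
    # smear across its edges
    sm <- stats::filter(yw, rep(1 / smooth_n, smooth_n), sides = 2)
    yw <- ifelse(is.na(sm), yw, as.numeric(sm))
  }
  j <- switch(polarity,
              auto = which.max(abs(yw)),
              positive = which.max(yw),
              negative = which.min(yw))
  list(peak_uA = yw[j], t_peak_ms = time_ms[idx[j]], index = idx[j])
}

#' Convert a peak current to a conductance
#'
#' `G = I / (Vm - Erev)` with the Nernst reversal potential from the ionic
#' conditions: the chord conductance of an ohmic K+ pore. The unit is uA
#' per mV of driving force (mS). Voltages closer to the reversal potential
#' than `floor_mV` are rejected (the division is ill-conditioned there);
#' callers flag and exclude such points from G-V curves.
#'
#' @param i_uA peak current in uA (vectorized).
#' @param vm_mV membrane voltage(s) in mV.
#' @param conditions an [ionic_conditions()] object.
#' @param k a [gating_constants()] object.
#' @param floor_mV minimum tolerated |Vm - Erev|.
#' @return Conductance(s) in uA/mV; `NA` where the driving force is below
#'   the floor.
#' @export
conductance_from_peak <- function(i_uA, vm_mV, conditions,
                                  k = gating_constants(temperature_K = conditions$temperature_K),
                                  floor_mV = 1) {
  stopifnot(inherits(conditions, "ionic_conditions"),
            length(i_uA) == length(vm_mV))
  erev <- nernst_mV(conditions, as_gating_constants(k))
  drive <- vm_mV - erev
  out <- ifelse(abs(drive) < floor_mV, NA_real_, i_uA / drive)
  attr(out, "erev_mV") <- erev
  out
}

#' Time-integrate a gating current to charge
#'
#' Trapezoidal integral of the baseline-subtracted current over a window,
#' in nC (uA x ms). The baseline is the mean current over a reference
#' window, by default the final 20 percent of the segment preceding the
#' integration window, which compensates any residual holding current and
#' makes the charge invariant to constant offsets.
#'
#' @param time_ms,current_uA the trace.
#' @param window `c(t0, t1)` integration window in ms.
#' @param baseline `"pre"` (default policy above), `"none"`, or a numeric
#'   `c(t0, t1)` window to average over.
#' @return Charge in nC.
#' @export
integrate_charge <- function(time_ms, current_uA, window, baseline = "pre") {
  stopifnot(length(time_ms) == length(current_uA), length(window) == 2L,
            window[2] > window[1])
  if (window[1] < time_ms[1] - 1e-9 || window[2] > time_ms[length(time_ms)] + 1e-9) {
    stop("integration window outside the sweep", call. = FALSE)
  }
  idx <- which(time_ms >= window[1] & time_ms <= window[2])
  if (length(idx) < 2L) stop("integration window too narrow", call. = FALSE)
  b <- 0
  if (is.numeric(baseline)) {
    bi <- which(time_ms >= baseline[1] & time_ms <= baseline[2])
    if (length(bi) == 0L) stop("empty baseline window", call. = FALSE)
    b <- mean(current_uA[bi])
  } else if (identical(baseline, "pre")) {
    pre <- which(time_ms < window[1])
    if (length(pre) > 0L) {
      # final 20% of the pre-window segment
      span <- window[1] - time_ms[pre[1]]
      bi <- pre[time_ms[pre] >= window[1] - 0.2 * span]
      b <- mean(current_uA[bi])
    }
  } else if (!identical(baseline, "none")) {
    stop("unknown baseline policy", call. = FALSE)
  }
  pracma::trapz(time_ms[idx], current_uA[idx] - b)
}

#' Fit a biexponential to a current decay
#'
#' Least-squares fit of `y0 - A1 exp(-t'/tau1) - A2 exp(-t'/tau2)` to the
#' decaying phase of a current, with `t'` measured from the start of the
#' fit window (by default the first sample after the absolute peak inside
#' `window`; earliest sample on ties). Initialization uses log-spaced time
#' constants between 1/50 and 1/2 of the window length with amplitudes from
#' the ordinate range; three restarts are run and the lowest
#' sum-of-squared-residuals fit is kept. Components are returned ordered
#' `tau1 <= tau2`. If the biexponential fit fails to converge, a
#' single-exponential fallback is fitted and the result flagged.
#'
#' @param time_ms,current_uA the trace.
#' @param window `c(t0, t1)` in ms bounding the decay; the actual fit
#'   starts at the post-peak sample within it.
#' @param from_peak if `FALSE`, fit from `window[1]` instead of the peak.
#' @return A list of class `decay_fit`: `params` (a [biexp_params()]),
#'   `tau_w_ms` (weighted time constant), `fast_fraction`
#'   (`A1 / (A1 + A2)`), `ssr`, `converged`, `flag`.
#' @export
fit_decay <- function(time_ms, current_uA, window, from_peak = TRUE) {
  stopifnot(length(time_ms) == length(current_uA), length(window) == 2L)
  idx <- which(time_ms >= window[1] & time_ms <= window[2])
  if (length(idx) < 8L) stop("decay window too narrow to fit", call. = FALSE)
  y <- current_uA[idx]; tt <- time_ms[idx]
  if (from_peak) {
    pk <- which.max(abs(y))[1]
    if (pk >= length(y) - 6L) stop("no decaying phase after the peak", call. = FALSE)
    y <- y[(pk + 1L):length(y)]
    tt <- tt[(pk + 1L):length(tt)]
  }
  t0 <- tt[1]
  tr <- tt - t0
  W <- tr[length(tr)]
  drop <- y[1] - y[length(y)]            # total decay amplitude (signed)
  y0_init <- y[length(y)]
  taus <- exp(seq(log(W / 50), log(W / 2), length.out = 3))

  resid_fun <- function(par) {
    y - (par[1] - par[2] * exp(-tr / exp(par[3])) - par[4] * exp(-tr / exp(par[5])))
  }
  best <- NULL
  for (i in seq_along(taus)) {
    for (jf in seq_along(taus)) {
      if (jf <= i) next
      start <- c(y0_init, -0.6 * drop, log(taus[i]), -0.4 * drop, log(taus[jf]))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- sum(fit$fvec^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
  }
  flag <- ""
  if (is.null(best)) {
    # single-exponential fallback
    sfun <- function(par) y - (par[1] - par[2] * exp(-tr / exp(par[3])))
    fit <- minpack.lm::nls.lm(par = c(y0_init, -drop, log(W / 5)), fn = sfun,
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- fit$par
    pars <- biexp_params(y0 = p[1], a1 = p[2], tau1 = exp(p[3]), a2 = 0,
                         tau2 = exp(p[3]))
    return(structure(list(params = pars, tau_w_ms = exp(p[3]),
                          fast_fraction = 1, ssr = sum(fit$fvec^2),
                          converged = fit$info %in% 1:4,
                          flag = "single_exp_fallback", t0_ms = t0),
                     class = "decay_fit"))
  }
  p <- best$fit$par
  a <- c(p[2], p[4]); tau <- exp(c(p[3], p[5]))
  o <- order(tau)
  a <- a[o]; tau <- tau[o]
  pars <- biexp_params(y0 = p[1], a1 = a[1], tau1 = tau[1], a2 = a[2],
                       tau2 = tau[2])
  tw <- if (a[1] + a[2] == 0) NA_real_ else weighted_tau(pars)
  structure(list(params = pars, tau_w_ms = tw,
                 fast_fraction = if (a[1] + a[2] == 0) NA_real_ else a[1] / (a[1] + a[2]),
                 ssr = best$ssr, converged = best$fit$info %in% 1:4,
                 flag = flag, t0_ms = t0),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  p <- x$params
  cat("Biexponential decay fit:\n")
  cat(sprintf("  tau1 = %.4g, tau2 = %.4g ms (weighted tau = %.4g ms)\n",
              p$tau1, p$tau2, x$tau_w_ms))
  cat(sprintf("  A1 = %.4g, A2 = %.4g, y0 = %.4g (fast fraction %.3f)\n",
              p$a1, p$a2, p$y0, x$fast_fraction))
  if (nzchar(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

segment_window <- function(ss, sweep, segment) {
  segs <- protocol_segments(ss$protocol, sweep)
  r <- segs[segs$segment == segment, ]
  if (nrow(r) != 1L) stop("segment not found in protocol", call. = FALSE)
  c(r$t0, r$t1)
}

#' Reduce a sweep set to per-sweep measurements
#'
#' Applies the appropriate per-sweep reductions for the sweep kind and
#' returns one row per sweep:
#'
#' * gating sets: ON charge `Q_nC`, the baseline-subtracted time integral
#'   of the current over the test step (baseline from the end of the
#'   pre-pulse), and the OFF charge over the tail;
#' * ionic I-V/G-V sets: peak test current `peak_uA` and chord conductance
#'   `G_uA_per_mV`;
#' * ionic inactivation sets: peak current during the fixed test pulse
#'   (`peak_uA`), reported against the conditioning voltage, plus a
#'   biexponential decay fit of the long conditioning step when
#'   `fit_decays = TRUE`.
#'
#' @param ss a [sweep_set()].
#' @param fit_decays fit the decaying phase of long depolarizing steps
#'   (ionic sets only).
#' @param leak optional leak specification for [peak_current()].
#' @param floor_mV driving-force floor for [conductance_from_peak()].
#' @return A data.frame with columns `cell_id`, `voltage_mV` (the variable
#'   step voltage), `peak_uA`, `G_uA_per_mV`, `Q_nC`, `Q_off_nC`,
#'   `tau_w_ms`, `fast_fraction`, `flags`.
#' @export
measure_sweep_set <- function(ss, fit_decays = FALSE, leak = NULL,
                              floor_mV = 1) {
  stopifnot(inherits(ss, "sweep_set"))
  kind <- ss$metadata$kind %||% "ionic"
  proto <- ss$protocol
  nsw <- nrow(proto$sweeps)
  vvar <- if (proto$type == "iv") proto$sweeps$test_mV else proto$sweeps$cond_mV
  out <- data.frame(cell_id = ss$metadata$cell_id %||% "cell1",
                    voltage_mV = vvar,
                    peak_uA = NA_real_, G_uA_per_mV = NA_real_,
                    Q_nC = NA_real_, Q_off_nC = NA_real_,
                    tau_w_ms = NA_real_, fast_fraction = NA_real_,
                    flags = "", stringsAsFactors = FALSE)
  tm <- ss$time_ms
  for (s in seq_len(nsw)) {
    y <- ss$current_uA[, s]
    if (kind == "gating") {
      dt <- proto$sample_interval_ms
      # segments are half-open [t0, t1): keep the boundary sample with the
      # segment it steps into
      w_on <- segment_window(ss, s, "test") - c(0, dt)
      segs <- protocol_segments(proto, s)
      pre <- segs[which(segs$segment == "test") - 1L, ]
      out$Q_nC[s] <- integrate_charge(
        tm, y, w_on,
        baseline = c(pre$t1 - 0.2 * (pre$t1 - pre$t0), pre$t1 - dt))
      w_off <- segment_window(ss, s, "tail")
      out$Q_off_nC[s] <- integrate_charge(
        tm, y, w_off,
        baseline = c(w_on[1] + 0.8 * diff(w_on), w_on[2]))
    } else {
      w <- segment_window(ss, s, "test") - c(0, proto$sample_interval_ms)
      pk <- peak_current(tm, y, w, leak = leak,
                         voltage_mV = if (is.null(leak)) NULL else voltage_trace(ss, s))
      out$peak_uA[s] <- pk$peak_uA
      if (!is.null(ss$conditions)) {
        vtest <- proto$sweeps$test_mV[s]
        g <- conductance_from_peak(pk$peak_uA, vtest, ss$conditions,
                                   floor_mV = floor_mV)
        out$G_uA_per_mV[s] <- as.numeric(g)
        if (is.na(g)) out$flags[s] <- paste0(out$flags[s], "near_erev;")
      }
      if (fit_decays) {
        wd <- segment_window(ss, s,
                             if (proto$type == "inactivation") "conditioning" else "test") -
          c(0, proto$sample_interval_ms)
        df <- tryCatch(fit_decay(tm, y, wd), error = function(e) NULL)
        if (!is.null(df)) {
          out$tau_w_ms[s] <- df$tau_w_ms
          out$fast_fraction[s] <- df$fast_fraction
          if (!df$converged || nzchar(df$flag)) {
            out$flags[s] <- paste0(out$flags[s], "decay_fit;")
          }
        } else {
          out$flags[s] <- paste0(out$flags[s], "decay_fit_failed;")
        }
      }
    }
  }
  out
}

#' Measure every cell of a cohort
#'
#' @param cohort a list of [sweep_set()]s from [simulate_cohort()] (or read
#'   from disk).
#' @param ... passed to [measure_sweep_set()].
#' @return Row-bound measurement table across cells.
#' @export
measure_cohort <- function(cohort, ...) {
  do.call(rbind, lapply(cohort, measure_sweep_set, ...))
}
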