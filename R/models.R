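#' Parameter containers for equilibrium gating models
#'
#' Small validated records holding fitted or generating parameters for the
#' closed-form gating curves. Standard errors are optional (`NA` when
#' unknown).
#'
#' @param z,z0,z1,z_inac apparent valences in elementary charges (e0); must
#'   be positive.
#' @param v_half,v0,v1,v_half_inac midpoint voltages in mV.
#' @param n scale of the three-state charge curve (proportional to the
#'   number of voltage sensors; `1/(z0+z1)` gives a curve normalized to 1).
#' @param a1,a2 minimum and maximum asymptotes of the availability curve
#'   (`a2 >= a1`).
#' @param se_z,se_v_half,se_z0,se_z1,se_v0,se_v1,se_n,se_a1,se_a2 optional
#'   standard errors.
#' @return A classed list (`two_state_params`, `three_state_params` or
#'   `inac_params`).
#' @name gating-params
NULL

#' @rdname gating-params
#' @export
two_state_params <- function(z, v_half, se_z = NA_real_, se_v_half = NA_real_) {
  stopifnot(is.finite(z), z > 0, is.finite(v_half))
  structure(list(z = z, v_half = v_half, se_z = se_z, se_v_half = se_v_half),
            class = "two_state_params")
}

#' @rdname gating-params
#' @export
three_state_params <- function(z0, v0, z1, v1, n = 1,
                               se_z0 = NA_real_, se_v0 = NA_real_,
                               se_z1 = NA_real_, se_v1 = NA_real_,
                               se_n = NA_real_) {
  stopifnot(is.finite(z0), z0 > 0, is.finite(z1), z1 > 0,
            is.finite(v0), is.finite(v1), is.finite(n), n > 0)
  structure(list(z0 = z0, v0 = v0, z1 = z1, v1 = v1, n = n,
                 se_z0 = se_z0, se_v0 = se_v0, se_z1 = se_z1, se_v1 = se_v1,
                 se_n = se_n),
            class = "three_state_params")
}

#' @rdname gating-params
#' @export
inac_params <- function(z_inac, v_half_inac, a1 = 0, a2 = 1,
                        se_z = NA_real_, se_v_half = NA_real_,
                        se_a1 = NA_real_, se_a2 = NA_real_) {
  stopifnot(is.finite(z_inac), z_inac > 0, is.finite(v_half_inac),
            is.finite(a1), is.finite(a2), a2 >= a1)
  structure(list(z_inac = z_inac, v_half_inac = v_half_inac, a1 = a1, a2 = a2,
                 se_z = se_z, se_v_half = se_v_half, se_a1 = se_a1, se_a2 = se_a2),
            class = "inac_params")
}

#' Biexponential decay parameters
#'
#' Parameters of the double-exponential decay used for C-type inactivation
#' time courses: `y(t) = y0 - A1 exp(-t/tau1) - A2 exp(-t/tau2)`.
#' Time constants must be positive; amplitudes may take either sign (a
#' current decaying from a peak toward a lower plateau has negative `A`s
#' under this sign convention).
#'
#' @param y0 baseline (value approached as `t -> Inf`).
#' @param a1,a2 amplitudes of the two components.
#' @param tau1,tau2 time constants (ms unless a dataset declares otherwise);
#'   both `> 0`.
#' @return An object of class `biexp_params`.
#' @export
biexp_params <- function(y0, a1, tau1, a2 = 0, tau2 = tau1) {
  stopifnot(is.finite(y0), is.finite(a1), is.finite(a2),
            is.finite(tau1), tau1 > 0, is.finite(tau2), tau2 > 0)
  structure(list(y0 = y0, a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2),
            class = "biexp_params")
}

check_vm <- function(vm) {
  if (!is.numeric(vm) || length(vm) == 0L || any(!is.finite(vm))) {
    stop("membrane voltages must be finite numbers", call. = FALSE)
  }
  vm
}

# Shared two-state Boltzmann kernel: identical function of (z, v_half) for
# conductance and charge curves.
boltzmann_kernel <- function(z, v_half, vm, k) {
  1 / (1 + clip_exp(z * (v_half - vm) * k$F_over_RT))
}

#' Equilibrium gating curves
#'
#' Closed-form voltage dependence of channel gating at equilibrium. These
#' are the forward models used both by the synthetic-sweep generator and by
#' the curve fitters.
#'
#' * `gv_two_state()` and `qv_two_state()` evaluate the two-state Boltzmann
#'   `1 / (1 + exp(z (V1/2 - Vm) F/RT))` for normalized conductance and
#'   normalized gating charge respectively; they share one kernel and are
#'   numerically identical functions of `(z, v_half)`.
#' * `qv_three_state()` evaluates the lumped sequential three-state charge
#'   curve
#'   `Q(Vm) = N [z1 + z0 (1 + e1)] / [(1 + e1)(1 + e0)]` with
#'   `ei = exp(zi (Vi - Vm) F/RT)`, saturating at `N (z0 + z1)` for large
#'   depolarizations and at 0 for strong hyperpolarizations.
#' * `qv_three_state_sequential()` is an independent formulation from state
#'   occupancies: Boltzmann factors for the two sequential transitions give
#'   occupancies of the three states and the mean charge
#'   `z0 P1 + (z0 + z1) P2` (times `N`). It is shipped for cross-checking;
#'   the fitters use the closed form above.
#' * `inac_curve()` is the descending availability curve
#'   `A2 + (A1 - A2) / (1 + exp(z (V1/2 - Vm) F/RT))`, falling from `A2` at
#'   hyperpolarized voltages to `A1` at depolarized voltages.
#'
#' Exponent arguments are clipped at +/-700 so evaluation at extreme
#' voltages saturates instead of overflowing.
#'
#' @param p a parameter object of the matching class (see
#'   [two_state_params()], [three_state_params()], [inac_params()]).
#' @param vm membrane voltage(s) in mV; vectorized.
#' @param k a [gating_constants()] object.
#' @return Numeric vector the length of `vm`: a fraction in `[0, 1]` for the
#'   two-state curves, charge in units of `N * e0` for the three-state
#'   curve, available fraction for `inac_curve()`.
#' @examples
#' k <- gating_constants()
#' gv_two_state(two_state_params(z = 2.9, v_half = -26), vm = c(-80, -26, 40), k)
#' @name gating-curves
NULL

#' @rdname gating-curves
#' @export
gv_two_state <- function(p, vm, k = gating_constants()) {
  stopifnot(inherits(p, "two_state_params"))
  boltzmann_kernel(p$z, p$v_half, check_vm(vm), as_gating_constants(k))
}

#' @rdname gating-curves
#' @export
qv_two_state <- function(p, vm, k = gating_constants()) {
  stopifnot(inherits(p, "two_state_params"))
  boltzmann_kernel(p$z, p$v_half, check_vm(vm), as_gating_constants(k))
}

#' @rdname gating-curves
#' @export
qv_three_state <- function(p, vm, k = gating_constants()) {
  stopifnot(inherits(p, "three_state_params"))
  vm <- check_vm(vm)
  k <- as_gating_constants(k)
  e1 <- clip_exp(p$z1 * (p$v1 - vm) * k$F_over_RT)
  e0 <- clip_exp(p$z0 * (p$v0 - vm) * k$F_over_RT)
  p$n * (p$z1 + p$z0 * (1 + e1)) / ((1 + e1) * (1 + e0))
}

#' @rdname gating-curves
#' @export
qv_three_state_sequential <- function(p, vm, k = gating_constants()) {
  stopifnot(inherits(p, "three_state_params"))
  vm <- check_vm(vm)
  k <- as_gating_constants(k)
  # forward Boltzmann log-factors for C0 -> C1 -> C2; shift by the largest
  # log-weight so the partition sum never overflows
  a0 <- p$z0 * (vm - p$v0) * k$F_over_RT
  a1 <- p$z1 * (vm - p$v1) * k$F_over_RT
  lw <- cbind(0, a0, a0 + a1)
  m <- apply(lw, 1, max)
  w <- exp(pmax(lw - m, -700))
  unname(p$n * (p$z0 * w[, 2] + (p$z0 + p$z1) * w[, 3]) / rowSums(w))
}

#' @rdname gating-curves
#' @export
inac_curve <- function(p, vm, k = gating_constants()) {
  stopifnot(inherits(p, "inac_params"))
  vm <- check_vm(vm)
  k <- as_gating_constants(k)
  p$a2 + (p$a1 - p$a2) /
    (1 + clip_exp(p$z_inac * (p$v_half_inac - vm) * k$F_over_RT))
}

#' Biexponential decay and its weighted time constant
#'
#' `biexp_decay()` evaluates `y0 - A1 exp(-t/tau1) - A2 exp(-t/tau2)`, the
#' model fitted to the decaying phase of potassium currents during slow
#' (C-type) inactivation. `weighted_tau()` returns the amplitude-weighted
#' mean time constant `(A1 tau1 + A2 tau2) / (A1 + A2)` used to summarize a
#' biexponential decay with one number.
#'
#' @param p a [biexp_params()] object.
#' @param t time (same unit as the tau's); vectorized.
#' @return `biexp_decay()`: numeric vector; `weighted_tau()`: a single time
#'   constant.
#' @examples
#' weighted_tau(biexp_params(y0 = 0, a1 = 1, tau1 = 2, a2 = 3, tau2 = 6)) # 5
#' @export
biexp_decay <- function(p, t) {
  stopifnot(inherits(p, "biexp_params"), is.numeric(t), all(is.finite(t)))
  p$y0 - p$a1 * exp(-t / p$tau1) - p$a2 * exp(-t / p$tau2)
}

#' @rdname biexp_decay
#' @export
weighted_tau <- function(p) {
  stopifnot(inherits(p, "biexp_params"))
  s <- p$a1 + p$a2
  if (s == 0) stop("weighted tau undefined: amplitudes sum to zero", call. = FALSE)
  (p$a1 * p$tau1 + p$a2 * p$tau2) / s
}
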