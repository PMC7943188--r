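test_that("peak detection finds the extremum of smooth and noisy traces", {
  tm <- seq(0, 100, 0.05)
  rising <- 5 * (1 - exp(-tm / 10))        # monotone: peak at window end
  pk <- peak_current(tm, rising, c(20, 80))
  expect_equal(pk$t_peak_ms, 80)
  expect_equal(pk$peak_uA, 5 * (1 - exp(-8)), tolerance = 1e-3)

  expect_error(peak_current(tm, rising, c(200, 300)), "empty")

  set.seed(4)
  noise_sd <- 0.05
  bumpy <- 3 * exp(-(tm - 40)^2 / 200) + rnorm(length(tm), 0, noise_sd)
  pk2 <- peak_current(tm, bumpy, c(0, 100))
  expect_lt(abs(pk2$peak_uA - 3), 2 * noise_sd)
  expect_lt(abs(pk2$t_peak_ms - 40), 10)

  # a pure leak trace vanishes after leak subtraction
  v <- rep(30, length(tm))
  leaky <- 0.02 * v + rnorm(length(tm), 0, noise_sd)
  pk3 <- peak_current(tm, leaky, c(10, 90), leak = list(g = 0.02),
                      voltage_mV = v)
  expect_lt(abs(pk3$peak_uA), 3 * noise_sd)
})

test_that("conductance conversion uses the Nernst driving force and round-trips", {
  sym <- ionic_conditions(120, 120)
  expect_equal(as.numeric(conductance_from_peak(2, 20, sym)), 0.1)
  expect_equal(as.numeric(conductance_from_peak(0, 20, sym)), 0)
  asym <- ionic_conditions(k_in_mM = 120, k_out_mM = 12)
  g <- conductance_from_peak(1, 20, asym)
  expect_equal(as.numeric(g), 1 / (20 - nernst_mV(asym)))
  expect_equal(20 - attr(g, "erev_mV"), 77.77, tolerance = 1e-2)
  # round trip G * (Vm - Erev) = I
  expect_equal(as.numeric(g) * (20 - attr(g, "erev_mV")), 1)
  # near the reversal potential the conversion is refused
  expect_true(is.na(conductance_from_peak(1, attr(g, "erev_mV") + 0.5, asym)))
})

test_that("charge integration is exact on rectangles, linear, and offset-invariant", {
  tm <- seq(0, 50, 0.05)
  rect <- ifelse(tm >= 10 & tm <= 20, 1, 0)
  expect_equal(integrate_charge(tm, rect, c(10, 20), baseline = "none"), 10,
               tolerance = 1e-10)
  expect_equal(integrate_charge(tm, rep(0, length(tm)), c(10, 20),
                                baseline = "none"), 0)
  expect_error(integrate_charge(tm, rect, c(40, 60)), "outside")

  s1 <- sin(tm / 5); s2 <- exp(-tm / 9)
  q <- function(y) integrate_charge(tm, y, c(5, 45), baseline = "none")
  expect_equal(q(2 * s1 + 3 * s2), 2 * q(s1) + 3 * q(s2), tolerance = 1e-12)

  # constant offsets cancel when the baseline comes from the pre-window
  y <- ifelse(tm >= 25, exp(-(tm - 25) / 3), 0)
  q0 <- integrate_charge(tm, y, c(25, 50), baseline = "pre")
  q1 <- integrate_charge(tm, y + 0.37, c(25, 50), baseline = "pre")
  expect_equal(q0, q1, tolerance = 1e-9)
})

test_that("biexponential decay fits recover known kinetics", {
  tm <- seq(0, 400, 0.5)
  truth <- biexp_params(y0 = 0.5, a1 = -2, tau1 = 15, a2 = -1, tau2 = 120)
  y <- biexp_decay(truth, tm)
  f <- fit_decay(tm, y, c(0, 400), from_peak = FALSE)
  expect_lt(f$ssr, 1e-8)
  expect_equal(f$params$tau1, 15, tolerance = 1e-4)
  expect_equal(f$params$tau2, 120, tolerance = 1e-4)
  expect_equal(f$tau_w_ms, weighted_tau(truth), tolerance = 1e-4)
  expect_equal(f$fast_fraction, 2 / 3, tolerance = 1e-4)

  # single-exponential input: degenerate but the weighted tau is right
  ys <- 1 - 0.8 * exp(-tm / 40)
  fs <- fit_decay(tm, ys, c(0, 400), from_peak = FALSE)
  expect_equal(fs$tau_w_ms, 40, tolerance = 0.01)
})

test_that("decay fit recovers the weighted tau from a simulated long pulse", {
  p <- make_protocol("inactivation", v_from = 40, v_to = 40, v_step = 10,
                     step_ms = 19000)
  gv <- two_state_params(2.9, -26)
  inac <- list(params = inac_params(4.6, -36, a1 = 0.05, a2 = 1),
               f_fast = 0.6, tau_fast_ms = 900, tau_slow_ms = 5000)
  ss <- simulate_ionic_sweeps(gv, p, ionic_conditions(120, 12),
                              act_tau_ms = 3, inac = inac,
                              noise_sd_uA = 0.02, seed = 8)
  m <- measure_sweep_set(ss, fit_decays = TRUE)
  # the fitted envelope mixes the two generator components with weights
  # f_fast * deficit: expected weighted tau at the conditioning voltage
  tw_true <- 0.6 * 900 + 0.4 * 5000
  expect_lt(abs(m$tau_w_ms[1] - tw_true) / tw_true, 0.10)
  expect_lt(abs(m$fast_fraction[1] - 0.6), 0.1)
})
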