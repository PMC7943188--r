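test_that("process free energy and its error propagation are correct", {
  e <- process_energy(z = 13.6, v_mV = -44.29, se_z = 0, se_v = 1.24)
  expect_equal(round(e$G, 2), -13.90)
  expect_equal(process_energy(5, 0)$G, 0)
  # quadrature of the two error terms
  e2 <- process_energy(2, -50, se_z = 0.1, se_v = 3)
  k <- gating_constants()
  expect_equal(e2$se,
               k$faraday_kcal / 1000 * sqrt((0.1 * -50)^2 + (3 * 2)^2))
  # with se_z = 0 the per-fit error formula coincides with the
  # median-voltage error formula zF dV
  e3 <- process_energy(13.6, -44.29, se_z = 0, se_v = 1.24)
  g3 <- gia_energy(median_charge(-44.29, 1.24, 13.6))
  expect_equal(e3$se, g3$se)
  expect_equal(e3$se, 13.6 * k$faraday_kcal * 1.24 / 1000)
})

test_that("energy shifts combine errors in quadrature and flag at the threshold", {
  a <- process_energy(2, -50, se_z = 0.1, se_v = 2)
  s0 <- energy_shift(a, a)
  expect_equal(s0$shift, 0)
  expect_false(s0$significant)
  expect_equal(s0$se, sqrt(2) * a$se)
  z0 <- energy_shift(process_energy(2, -50), process_energy(2, -72))
  expect_equal(z0$se, 0)
  expect_true(z0$significant)  # ~1.0 kcal/mol shift
  expect_equal(z0$shift, 2 * gating_constants()$faraday_kcal * 22 / 1000)
})

test_that("median voltage matches V1/2 for symmetric curves and is equivariant", {
  v <- seq(-200, 40, 1)
  p <- two_state_params(1.8, -80)
  cv <- as_normalized_curve(v, qv_two_state(p, v, kc))
  m <- median_voltage(cv)
  expect_lt(abs(m$v_median_mV - (-80)), 0.1)
  expect_equal(m$se_mV, 0)

  shifted <- as_normalized_curve(v + 10, qv_two_state(p, v, kc))
  expect_equal(median_voltage(shifted)$v_median_mV, m$v_median_mV + 10,
               tolerance = 1e-9)

  short <- as_normalized_curve(seq(-90, -70, 1),
                               qv_two_state(p, seq(-90, -70, 1), kc))
  expect_error(median_voltage(short), "saturation")
})

test_that("median voltage agrees with a 0.01 mV brute-force area-balance oracle", {
  p2 <- two_state_params(1.1, -89.8)
  f2 <- function(v) qv_two_state(p2, v, kc)
  v <- seq(-220, 40, 2)
  m2 <- median_voltage(as_normalized_curve(v, f2(v)))
  expect_lt(abs(m2$v_median_mV - median_oracle(f2, -220, 40)), 0.1)

  p3 <- three_state_params(1.7, -51.9, 3.4, -46.5, n = 1 / 5.1)
  f3 <- function(v) qv_three_state(p3, v, kc) # asymmetric: median != midpoint
  v3 <- seq(-160, 40, 2)
  m3 <- median_voltage(as_normalized_curve(v3, f3(v3)))
  expect_lt(abs(m3$v_median_mV - median_oracle(f3, -160, 40)), 0.1)
})

test_that("median-voltage free energies reproduce the published cycle table", {
  tab <- shaker_median_table()
  Gs <- vapply(seq_len(nrow(tab)), function(i) {
    gia_energy(median_charge(tab$v_median_mV[i], tab$se_mV[i]))$G
  }, numeric(1))
  expect_equal(round(Gs, 2), c(-13.90, -15.24, -17.06, -16.39))
  expect_equal(gia_energy(median_charge(-48.54, 0))$se, 0)
})

test_that("the mutant cycle is symmetric, shift-invariant, and zero for additive energies", {
  m <- function(v) median_charge(v, 0.5)
  cyc <- mutant_cycle(m(-50), m(-55), m(-60), m(-62))
  swapped <- mutant_cycle(m(-50), m(-60), m(-55), m(-62))
  expect_equal(cyc$ddG, swapped$ddG)
  expect_equal(cyc$se, swapped$se)

  shifted <- mutant_cycle(m(-40), m(-45), m(-50), m(-52))
  expect_equal(shifted$ddG, cyc$ddG, tolerance = 1e-12)

  # perfectly additive double mutant
  add <- mutant_cycle(m(-50), m(-55), m(-60), m(-65))
  expect_equal(add$ddG, 0, tolerance = 1e-12)
  expect_false(add$interacting)

  same <- mutant_cycle(m(-50), m(-50), m(-50), m(-50))
  expect_equal(same$ddG, 0)
  expect_false(same$interacting)

  expect_error(mutant_cycle(m(-50), m(-55), m(-60),
                            median_charge(-62, 0.5, z_total = 12)),
               "z_total")
})

test_that("per-process shift report flags the published significance pattern", {
  tab <- shaker_fit_table()
  ala <- c("L409A", "S411A", "S412A", "F433A")

  q2 <- shift_report(tab, "Q2", reference = "W434F",
                     mutants = paste0(ala, ":W434F"))
  expect_equal(q2$significant, c(FALSE, FALSE, FALSE, TRUE))
  # the one significant second-transition shift is ~1.7-1.8 kcal/mol
  expect_gt(q2$shift_kcal[4], 1.6)
  expect_lt(q2$shift_kcal[4], 2.0)

  g <- shift_report(tab, "G", reference = "WT", mutants = ala)
  expect_equal(g$significant, c(TRUE, TRUE, FALSE, TRUE))

  inac <- shift_report(tab, "Inac", reference = "WT", mutants = ala)
  expect_equal(inac$significant, c(TRUE, FALSE, TRUE, TRUE))
})
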