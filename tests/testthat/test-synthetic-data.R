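test_that("protocol builder counts sweeps and validates input", {
  p <- make_protocol("iv", v_from = -120, v_to = 60, v_step = 10)
  expect_s3_class(p, "voltage_protocol")
  expect_equal(nrow(p$sweeps), 19)
  expect_equal(p$sweeps$test_mV, seq(-120, 60, 10))

  pin <- make_protocol("inactivation", v_from = -100, v_to = 20, v_step = 20)
  expect_equal(pin$segments$duration_ms[pin$segments$segment == "conditioning"],
               19000)
  expect_true(all(pin$sweeps$test_mV == 60))
  expect_equal(pin$sample_interval_ms, 1)

  expect_error(make_protocol("iv", v_from = 0, v_to = -10, v_step = 10),
               "empty|wrong sign")
  expect_error(make_protocol("iv", v_from = -120, v_to = 60, v_step = 10,
                             step_ms = 50.3, sample_interval_ms = 0.4),
               "divide")
})

test_that("noiseless gating sweeps integrate to the equilibrium charge difference", {
  p <- make_protocol("iv", v_from = -160, v_to = 0, v_step = 20,
                     prepulse_mV = -160)
  qv <- two_state_params(1.1, -89.8)
  ss <- simulate_gating_sweeps(qv, p, qmax_nC = 2, noise_sd_uA = 0, seed = 3)
  m <- measure_sweep_set(ss)
  dq <- 2 * (qv_two_state(qv, m$voltage_mV, kc) - qv_two_state(qv, -160, kc))
  keep <- abs(dq) > 0.02
  expect_lt(max(abs(m$Q_nC[keep] - dq[keep]) / abs(dq[keep])), 1e-3)
  # ON/OFF conservation (first-order kinetics are conservative)
  expect_lt(max(abs((m$Q_nC[keep] + m$Q_off_nC[keep]) / m$Q_nC[keep])), 5e-3)
})

test_that("a step to the pre-pulse voltage yields a zero-mean trace", {
  p <- make_protocol("iv", v_from = -160, v_to = -160, v_step = 10,
                     prepulse_mV = -160)
  ss <- simulate_gating_sweeps(two_state_params(1.5, -80), p, noise_sd_uA = 0,
                               seed = 1)
  tst <- ss$time_ms > 60  # past the holding->prepulse relaxation
  expect_lt(max(abs(ss$current_uA[tst, 1])), 1e-6)
})

test_that("seeds control reproducibility and truth records everything but noise", {
  p <- make_protocol("iv", v_from = -120, v_to = -40, v_step = 40)
  qv <- two_state_params(1.5, -80)
  a <- simulate_gating_sweeps(qv, p, seed = 11)
  b <- simulate_gating_sweeps(qv, p, seed = 11)
  c <- simulate_gating_sweeps(qv, p, seed = 12)
  expect_identical(a$current_uA, b$current_uA)
  expect_false(identical(a$current_uA, c$current_uA))
  ta <- a$truth; tc <- c$truth
  ta$seed <- NULL; tc$seed <- NULL
  expect_identical(ta, tc)
  expect_error(simulate_gating_sweeps(qv, p), "seed")
  expect_error(simulate_gating_sweeps(qv, p, tau_ms = 0.05, seed = 1),
               "sample intervals")
})

test_that("ionic sweeps obey the Nernst driving force", {
  expect_equal(nernst_mV(ionic_conditions(120, 120)), 0)
  expect_equal(nernst_mV(ionic_conditions(k_in_mM = 120, k_out_mM = 12)),
               kc$kT_mV * log(0.1), tolerance = 1e-12)
  expect_equal(nernst_mV(ionic_conditions(120, 12)), -57.77, tolerance = 1e-3)

  # symmetric K+: current reverses at 0 mV
  p <- make_protocol("iv", v_from = -20, v_to = 20, v_step = 20,
                     prepulse_mV = -140)
  gv <- two_state_params(2.0, -52)
  ss <- simulate_ionic_sweeps(gv, p, ionic_conditions(120, 120),
                              noise_sd_uA = 0, seed = 5)
  m <- measure_sweep_set(ss)
  expect_lt(m$peak_uA[m$voltage_mV == -20], 0)
  expect_equal(m$peak_uA[m$voltage_mV == 0], 0, tolerance = 1e-9)
  expect_gt(m$peak_uA[m$voltage_mV == 20], 0)
})

test_that("without inactivation the peak current matches gmax * gv * driving force", {
  p <- make_protocol("iv", v_from = -60, v_to = 40, v_step = 20,
                     prepulse_mV = -140)
  gv <- two_state_params(1.6, -52.5)
  cond <- ionic_conditions(120, 12)
  ss <- simulate_ionic_sweeps(gv, p, cond, gmax_uA_per_mV = 0.05,
                              noise_sd_uA = 0, seed = 2)
  m <- measure_sweep_set(ss)
  erev <- nernst_mV(cond)
  pred <- 0.05 * gv_two_state(gv, m$voltage_mV, kc) * (m$voltage_mV - erev)
  expect_equal(m$peak_uA, pred, tolerance = 1e-3)
})

test_that("leak current is exactly linear in voltage", {
  p <- make_protocol("iv", v_from = -100, v_to = 60, v_step = 20,
                     prepulse_mV = -140)
  ss <- simulate_ionic_sweeps(two_state_params(2, -40), p,
                              ionic_conditions(120, 120),
                              gmax_uA_per_mV = 1e-30, g_leak_uA_per_mV = 0.01,
                              noise_sd_uA = 0, seed = 9)
  v <- p$sweeps$test_mV
  mid <- which(ss$time_ms > 80 & ss$time_ms < 100)
  i_mid <- colMeans(ss$current_uA[mid, ])
  expect_equal(i_mid, 0.01 * v, tolerance = 1e-12)
})

test_that("cohorts scatter the scale but not the normalized curve", {
  p <- make_protocol("iv", v_from = -160, v_to = 0, v_step = 20,
                     prepulse_mV = -160)
  qv <- two_state_params(1.5, -80)
  one <- simulate_cohort("gating", qv, p, n_cells = 1, seed = 21,
                         noise_sd_uA = 0)
  one2 <- simulate_cohort("gating", qv, p, n_cells = 1, seed = 21,
                          noise_sd_uA = 0)
  expect_length(one, 1)
  expect_identical(one[[1]]$current_uA, one2[[1]]$current_uA)

  flat <- simulate_cohort("gating", qv, p, n_cells = 4, scatter_sdlog = 0,
                          seed = 22, noise_sd_uA = 0)
  cvs <- build_curve(measure_cohort(flat), "QV")
  expect_equal(max(cvs$sem), 0, tolerance = 1e-12)

  sc <- simulate_cohort("gating", qv, p, n_cells = 8, scatter_sdlog = 0.3,
                        seed = 23, noise_sd_uA = 0.02)
  qmax <- vapply(sc, function(s) max(measure_sweep_set(s)$Q_nC), numeric(1))
  expect_gt(diff(range(qmax)), 0.1)          # maxima differ across cells
  cv <- build_curve(measure_cohort(sc), "QV")
  truth <- qv_two_state(qv, cv$voltage_mV, kc) / qv_two_state(qv, 0, kc)
  expect_lt(max(abs(cv$mean - truth)), 0.05) # normalized curves agree
})

test_that("sweep sets round-trip through the CSV/JSON container", {
  p <- make_protocol("iv", v_from = -120, v_to = -60, v_step = 30)
  ss <- simulate_gating_sweeps(two_state_params(1.5, -80), p, seed = 31,
                               label = "demo")
  d <- withr::local_tempdir()
  write_sweep_set(ss, file.path(d, "demo_cell01"))
  back <- read_sweep_set(file.path(d, "demo_cell01"))
  expect_equal(back$current_uA, ss$current_uA, tolerance = 1e-12)
  expect_equal(back$time_ms, ss$time_ms)
  expect_equal(back$protocol$sweeps, ss$protocol$sweeps)
  expect_equal(back$metadata$cell_id, ss$metadata$cell_id)
  expect_equal(measure_sweep_set(back), measure_sweep_set(ss),
               tolerance = 1e-10)
})
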