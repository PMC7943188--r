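test_that("curve building normalizes per cell, averages, and is idempotent", {
  v <- seq(-120, 40, 20)
  base <- qv_two_state(two_state_params(1.5, -60), v, kc)
  one <- data.frame(cell_id = "a", voltage_mV = v, Q_nC = 2.2 * base)
  cv1 <- build_curve(one, "QV")
  expect_equal(cv1$n_cells, 1)
  expect_equal(cv1$sem, rep(0, length(v)))
  expect_equal(max(cv1$mean), 1)

  # cells identical up to scale collapse to one normalized curve
  multi <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(cell_id = paste0("c", i), voltage_mV = v, Q_nC = i * base)
  }))
  cvm <- build_curve(multi, "QV")
  expect_equal(cvm$mean, base / max(base), tolerance = 1e-12)
  expect_equal(max(cvm$sem), 0, tolerance = 1e-12)

  # idempotence: renormalizing a normalized curve changes nothing
  expect_identical(build_curve(cvm, "QV"), cvm)
  expect_error(build_curve(one[0, ], "QV"), "no cells")
})

test_that("cohort mean curves track the generating model within their SEM", {
  v <- seq(-140, 20, 10)
  p <- two_state_params(1.8, -60)
  hits <- 0; total <- 0
  for (r in 1:20) {
    meas <- synthetic_qv_measurements(p, v, n_cells = 6, sd = 0.02,
                                      seed = 100 + r)
    cv <- build_curve(meas, "QV")
    truth <- qv_two_state(p, v, kc) / max(qv_two_state(p, v, kc))
    # max-normalization deflates every cell by its noisy maximum; align the
    # overall scale first, then judge pointwise agreement against the SEM
    sc <- sum(truth * cv$mean) / sum(cv$mean^2)
    crit <- qt(0.975, df = cv$n_cells - 1)  # small-n interval, not +/-2 SD
    ok <- abs(sc * cv$mean - truth) <= crit * sc * pmax(cv$sem, 1e-3)
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gt(hits / total, 0.90)
})

test_that("each fitter recovers its own noiseless parameters exactly", {
  v <- seq(-140, 40, 5)
  fg <- fit_gv(model_curve(two_state_params(1.6, -52.5), v, "GV"), k = kc)
  expect_equal(unname(coef(fg)[c("z", "v_half")]), c(1.6, -52.5),
               tolerance = 1e-7)

  vq <- seq(-160, 0, 5)
  fq <- fit_qv(model_curve(two_state_params(1.0, -81.5), vq), "two_state", k = kc)
  expect_equal(unname(coef(fq)[c("z", "v_half")]), c(1.0, -81.5),
               tolerance = 1e-7)

  p3 <- three_state_params(1.7, -51.9, 3.4, -46.5, n = 1 / (1.7 + 3.4))
  f3 <- fit_qv(model_curve(p3, seq(-120, 20, 5)), "three_state", k = kc)
  expect_equal(unname(coef(f3)[c("z0", "v0", "z1", "v1")]),
               c(1.7, -51.9, 3.4, -46.5), tolerance = 1e-6)

  vi <- seq(-80, 20, 5)
  fi <- fit_inacv(model_curve(inac_params(4.6, -36, 0, 1), vi, "InacV"), k = kc)
  expect_equal(unname(coef(fi)[c("z", "v_half", "a1", "a2")]),
               c(4.6, -36, 0, 1), tolerance = 1e-6)
  expect_gte(coef(fi)["a1"], 0)
})

test_that("degenerate inputs are rejected", {
  v <- seq(-100, 0, 10)
  flat <- as_normalized_curve(v, rep(0.5, length(v)), "GV")
  expect_error(fit_gv(flat, k = kc), "flat")
  few <- as_normalized_curve(c(-80, -60, -40, -20, 0),
                             c(0.02, 0.2, 0.5, 0.8, 0.98), "QV")
  expect_error(fit_qv(few, "three_state", k = kc), "under-determined")
})

test_that("a two-state fit to three-state data underestimates the total charge", {
  p3 <- three_state_params(z0 = 1.7, v0 = -90, z1 = 3.4, v1 = -40,
                           n = 1 / 5.1)
  v <- seq(-160, 20, 5)
  f2 <- fit_qv(model_curve(p3, v), "two_state", k = kc)
  expect_true(f2$converged)
  expect_lt(coef(f2)["z"], 1.7 + 3.4)
})

test_that("model selection separates monophasic from biphasic charge curves", {
  v <- seq(-160, 20, 10)
  two <- model_curve(two_state_params(1.2, -80), v)
  sel2 <- model_select_qv(two, k = kc)
  expect_equal(sel2$model, "two_state")

  biph <- model_curve(three_state_params(2.5, -110, 3.5, -40, n = 1 / 6), v)
  sel3 <- model_select_qv(biph, k = kc)
  expect_equal(sel3$model, "three_state")

  forced <- model_select_qv(biph, override = "two_state", k = kc)
  expect_equal(forced$model, "two_state")
})

test_that("fit standard errors shrink like 1/sqrt(n_cells)", {
  v <- seq(-140, 20, 10)
  p <- two_state_params(1.8, -60)
  mean_se <- function(n_cells) {
    ses <- vapply(1:30, function(r) {
      meas <- synthetic_qv_measurements(p, v, n_cells, sd = 0.03,
                                        seed = 7000 + 37 * r + n_cells)
      fit_gv(build_curve(meas, "QV"), k = kc)$se["v_half"]
    }, numeric(1))
    mean(ses)
  }
  ratio <- mean_se(3) / mean_se(12)
  expect_equal(ratio, 2, tolerance = 0.25)
})

test_that("gating_fit methods are coherent", {
  v <- seq(-140, 20, 10)
  cv <- model_curve(two_state_params(1.8, -60), v, "GV")
  f <- fit_gv(cv, k = kc)
  expect_s3_class(f, "gating_fit")
  expect_equal(predict(f), unname(fitted(f)))
  expect_equal(fitted(f) + residuals(f), cv$mean, tolerance = 1e-12)
  expect_equal(dim(vcov(f)), c(3, 3))  # z, v_half, free scale
  expect_output(print(f), "two_state")
  expect_output(print(summary(f)), "Gating model fit")
  pars <- fit_params(f)
  expect_s3_class(pars, "two_state_params")
  expect_equal(unname(pars$z), unname(coef(f)["z"]))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(v), 3))
})
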