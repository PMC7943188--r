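# shared fixtures for the suite: constants and model-generated curves
kc <- gating_constants()

# noiseless normalized curve straight from a gating model
model_curve <- function(p, v, kind = "QV", k = kc) {
  y <- if (inherits(p, "two_state_params")) qv_two_state(p, v, k)
       else if (inherits(p, "three_state_params")) {
         qv_three_state(p, v, k) / (p$n * (p$z0 + p$z1))
       } else inac_curve(p, v, k)
  as_normalized_curve(v, y, kind = kind)
}

# per-cell measurement table drawn around a model curve (curve-level noise,
# for fitter-calibration tests that do not need the full sweep pipeline)
synthetic_qv_measurements <- function(p, v, n_cells, sd, seed, k = kc) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_cells), function(i) {
    scale <- stats::rlnorm(1, 0, 0.3)
    data.frame(cell_id = sprintf("c%02d", i), voltage_mV = v,
               Q_nC = scale * qv_two_state(p, v, k) + stats::rnorm(length(v), 0, sd))
  }))
}

# brute-force area-balance median oracle on a 0.01 mV grid: scans the
# cumulative trapezoid for the voltage where area below (1 - q) equals area
# above q, interpolating linearly at the crossing
median_oracle <- function(fun, v_lo, v_hi, dv = 0.01) {
  v <- seq(v_lo, v_hi, by = dv)
  q <- fun(v)
  q <- (q - min(q)) / (max(q) - min(q))
  below <- cumsum(c(0, (q[-1] + q[-length(q)]) / 2 * diff(v)))
  total_above <- (v[length(v)] - v) - (below[length(below)] - below)
  f <- below - total_above
  i <- which(f >= 0)[1]
  v[i - 1] + (0 - f[i - 1]) / (f[i] - f[i - 1]) * (v[i] - v[i - 1])
}
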