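#' @title Sweep sets
#' @description A `sweep_set` holds one voltage-clamp experiment: the pulse
#' protocol, optional ionic conditions, a shared time base (ms) and a
#' current matrix (uA) with one column per sweep. Simulated sets carry a
#' `truth` element (class `sim_truth`) recording every generating parameter
#' and the seed, so parameter-recovery tests can compare estimates against
#' ground truth.
#' @param protocol a [make_protocol()] object.
#' @param current numeric matrix, `length(time_ms)` rows, one column per
#'   protocol sweep.
#' @param conditions an [ionic_conditions()] object or `NULL` for gating
#'   (ion-free) recordings.
#' @param metadata list with at least `kind` (`"gating"` or `"ionic"`),
#'   `cell_id`, `label`, `seed`.
#' @param truth optional `sim_truth` list of generating parameters.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(protocol, current, conditions = NULL,
                      metadata = list(), truth = NULL) {
  stopifnot(inherits(protocol, "voltage_protocol"), is.matrix(current))
  tm <- protocol_times(protocol)
  if (nrow(current) != length(tm) || ncol(current) != nrow(protocol$sweeps)) {
    stop("current matrix does not match the protocol's time base / sweep count",
         call. = FALSE)
  }
  structure(
    list(protocol = protocol, conditions = conditions, time_ms = tm,
         current_uA = current, metadata = metadata, truth = truth),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set: %s, %d sweeps x %d samples, %.4g ms>\n",
              if (is.null(x$metadata$kind)) "?" else x$metadata$kind,
              ncol(x$current_uA), nrow(x$current_uA),
              protocol_total_ms(x$protocol)))
  if (!is.null(x$metadata$cell_id)) {
    cat(sprintf("  cell %s%s, seed %s\n", x$metadata$cell_id,
                if (nzchar(x$metadata$label %||% "")) paste0(" (", x$metadata$label, ")") else "",
                format(x$metadata$seed %||% NA)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-voltage trace of one sweep
#'
#' @param ss a [sweep_set()].
#' @param sweep sweep index.
#' @return Voltage (mV) at each sample of the shared time base.
#' @export
voltage_trace <- function(ss, sweep) {
  segs <- protocol_segments(ss$protocol, sweep)
  tm <- ss$time_ms
  v <- numeric(length(tm))
  for (i in seq_len(nrow(segs))) {
    idx <- if (i < nrow(segs)) tm >= segs$t0[i] & tm < segs$t1[i]
           else tm >= segs$t0[i]
    v[idx] <- segs$voltage_mV[i]
  }
  v
}

as_tau_fun <- function(tau) {
  if (is.function(tau)) return(tau)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  function(v) rep(tau, length(v))
}

# normalized equilibrium charge/open-probability in [0, 1]
normalized_eq_fun <- function(model, k) {
  if (inherits(model, "two_state_params")) {
    function(v) boltzmann_kernel(model$z, model$v_half, v, k)
  } else if (inherits(model, "three_state_params")) {
    qmax <- model$n * (model$z0 + model$z1)
    function(v) qv_three_state(model, v, k) / qmax
  } else {
    stop("model must be two_state_params or three_state_params", call. = FALSE)
  }
}

#' Simulate gating-current sweeps
#'
#' Generates the capacitive-like currents of voltage-sensor charge movement
#' under a step protocol. Within each protocol segment the normalized
#' sensor charge relaxes first-order from its value at the end of the
#' previous segment toward the equilibrium of the segment voltage
#' (`q_eq(V)` from the supplied two- or three-state model) with time
#' constant `tau_ms(V)`; the recorded current is `Qmax * dq/dt` (nC/ms =
#' uA). First-order relaxation makes the time integral of the noiseless ON
#' current over a step equal the closed-form equilibrium charge difference
#' `Qmax * [q_eq(V_step) - q_eq(V_pre)]`, which is all the downstream
#' analysis consumes. Additive white Gaussian noise and an optional
#' residual capacitive transient (decaying exponential at each step edge,
#' amplitude proportional to the voltage jump) can be superimposed.
#'
#' @param model a [two_state_params()] or [three_state_params()] charge
#'   model.
#' @param protocol a [make_protocol()] object.
#' @param qmax_nC maximum gating charge of the cell in nC.
#' @param tau_ms relaxation time constant: a positive scalar (ms) or a
#'   function of voltage returning ms. Must be at least twice the sample
#'   interval everywhere it is evaluated.
#' @param noise_sd_uA standard deviation of the additive current noise.
#' @param cap_amp_uA residual capacitive-transient amplitude per 100 mV of
#'   step (0 = fully compensated, the default).
#' @param cap_tau_ms decay time constant of the capacitive residual.
#' @param seed integer RNG seed; required, so every sweep set is
#'   reproducible.
#' @param cell_id,label metadata strings.
#' @return A [sweep_set()] with `truth` recording all generating
#'   parameters.
#' @examples
#' p <- make_protocol("iv", v_from = -160, v_to = 0, v_step = 20,
#'                    prepulse_mV = -160)
#' ss <- simulate_gating_sweeps(two_state_params(z = 1.1, v_half = -87.2),
#'                              p, seed = 1)
#' @export
simulate_gating_sweeps <- function(model, protocol, qmax_nC = 2,
                                   tau_ms = 2, noise_sd_uA = 0.02,
                                   cap_amp_uA = 0, cap_tau_ms = 0.5,
                                   seed, cell_id = "cell1", label = "",
                                   k = gating_constants()) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  stopifnot(inherits(protocol, "voltage_protocol"),
            is.finite(qmax_nC), qmax_nC > 0, noise_sd_uA >= 0)
  k <- as_gating_constants(k)
  q_eq <- normalized_eq_fun(model, k)
  tau_f <- as_tau_fun(tau_ms)
  dt <- protocol$sample_interval_ms
  tm <- protocol_times(protocol)
  nsw <- nrow(protocol$sweeps)
  cur <- matrix(0, nrow = length(tm), ncol = nsw)

  set.seed(seed)
  for (s in seq_len(nsw)) {
    segs <- protocol_segments(protocol, s)
    taus <- tau_f(segs$voltage_mV)
    if (any(taus < 2 * dt)) {
      stop("relaxation tau shorter than 2 sample intervals; refine sampling",
           call. = FALSE)
    }
    q <- q_eq(segs$voltage_mV[1])  # start at equilibrium of first segment
    trace <- numeric(length(tm))
    for (i in seq_len(nrow(segs))) {
      idx <- which(if (i < nrow(segs)) tm >= segs$t0[i] & tm < segs$t1[i]
                   else tm >= segs$t0[i])
      tr <- tm[idx] - segs$t0[i]
      qe <- q_eq(segs$voltage_mV[i])
      decay <- exp(-tr / taus[i])
      trace[idx] <- qmax_nC * (qe - q) * decay / taus[i]
      if (cap_amp_uA != 0 && i > 1) {
        dv <- segs$voltage_mV[i] - segs$voltage_mV[i - 1]
        trace[idx] <- trace[idx] +
          cap_amp_uA * (dv / 100) * exp(-tr / cap_tau_ms)
      }
      q <- qe + (q - qe) * exp(-(segs$t1[i] - segs$t0[i]) / taus[i])
    }
    cur[, s] <- trace
  }
  if (noise_sd_uA > 0) {
    cur <- cur + matrix(stats::rnorm(length(cur), 0, noise_sd_uA), nrow = nrow(cur))
  }
  truth <- structure(
    list(kind = "gating", model = model, qmax_nC = qmax_nC,
         tau_ms = tau_ms, noise_sd_uA = noise_sd_uA,
         cap_amp_uA = cap_amp_uA, cap_tau_ms = cap_tau_ms,
         seed = seed, constants = k),
    class = "sim_truth"
  )
  sweep_set(protocol, cur, conditions = NULL,
            metadata = list(kind = "gating", cell_id = cell_id,
                            label = label, seed = seed),
            truth = truth)
}

#' Simulate ionic potassium-current sweeps
#'
#' Generates macroscopic K+ currents under a step protocol. Open
#' probability is tracked with two first-order state variables: activation
#' relaxes toward the two-state Boltzmann equilibrium `gv(V)` with
#' `act_tau_ms(V)`, and (optionally) a slow-inactivation deficit split into
#' a fast and a slow component relaxes toward
#' `(1 - avail(V)) * (f_fast, 1 - f_fast)` with its own time constants, so
#' sustained depolarizations decay along a biexponential envelope toward the
#' steady-state availability curve. The recorded current is
#' `gmax * Po(t) * (Vm - Erev) + g_leak * Vm + noise`, with an ohmic driving
#' force and the Nernst reversal from the ionic conditions.
#'
#' @param model a [two_state_params()] conductance (G-V) model.
#' @param protocol a [make_protocol()] object.
#' @param conditions an [ionic_conditions()] object.
#' @param gmax_uA_per_mV maximal conductance, in uA of current per mV of
#'   driving force (i.e. mS); must be positive.
#' @param act_tau_ms activation time constant: scalar ms or function of
#'   voltage.
#' @param inac `NULL` for a non-inactivating channel, or a list with
#'   `params` (an [inac_params()] steady-state availability curve),
#'   `f_fast` (fraction of the inactivating amplitude in the fast
#'   component), `tau_fast_ms` and `tau_slow_ms`.
#' @param g_leak_uA_per_mV linear leak conductance (current `g_leak * Vm`).
#' @param noise_sd_uA additive white noise SD.
#' @param seed integer RNG seed (required).
#' @param cell_id,label metadata strings.
#' @param k a [gating_constants()] object.
#' @return A [sweep_set()] with generating `truth`.
#' @export
simulate_ionic_sweeps <- function(model, protocol, conditions = ionic_conditions(),
                                  gmax_uA_per_mV = 0.05, act_tau_ms = 2,
                                  inac = NULL, g_leak_uA_per_mV = 0,
                                  noise_sd_uA = 0.02, seed,
                                  cell_id = "cell1", label = "",
                                  k = gating_constants(temperature_K = conditions$temperature_K)) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  stopifnot(inherits(model, "two_state_params"),
            inherits(protocol, "voltage_protocol"),
            inherits(conditions, "ionic_conditions"))
  if (!is.finite(gmax_uA_per_mV) || gmax_uA_per_mV <= 0) {
    stop("`gmax_uA_per_mV` must be positive", call. = FALSE)
  }
  k <- as_gating_constants(k)
  erev <- nernst_mV(conditions, k)
  gv_eq <- function(v) boltzmann_kernel(model$z, model$v_half, v, k)
  act_f <- as_tau_fun(act_tau_ms)
  if (!is.null(inac)) {
    stopifnot(inherits(inac$params, "inac_params"),
              inac$f_fast >= 0, inac$f_fast <= 1,
              inac$tau_fast_ms > 0, inac$tau_slow_ms > 0)
  }
  dt <- protocol$sample_interval_ms
  tm <- protocol_times(protocol)
  nsw <- nrow(protocol$sweeps)
  cur <- matrix(0, nrow = length(tm), ncol = nsw)

  set.seed(seed)
  for (s in seq_len(nsw)) {
    segs <- protocol_segments(protocol, s)
    a <- gv_eq(segs$voltage_mV[1])
    if (is.null(inac)) {
      d1 <- 0; d2 <- 0
    } else {
      def0 <- 1 - inac_curve(inac$params, segs$voltage_mV[1], k)
      d1 <- inac$f_fast * def0; d2 <- (1 - inac$f_fast) * def0
    }
    trace <- numeric(length(tm))
    for (i in seq_len(nrow(segs))) {
      idx <- which(if (i < nrow(segs)) tm >= segs$t0[i] & tm < segs$t1[i]
                   else tm >= segs$t0[i])
      tr <- tm[idx] - segs$t0[i]
      v <- segs$voltage_mV[i]
      ta <- act_f(v)
      if (ta < 2 * dt) stop("activation tau shorter than 2 sample intervals",
                            call. = FALSE)
      ae <- gv_eq(v)
      a_t <- ae + (a - ae) * exp(-tr / ta)
      if (is.null(inac)) {
        avail_t <- 1
      } else {
        def <- 1 - inac_curve(inac$params, v, k)
        d1e <- inac$f_fast * def; d2e <- (1 - inac$f_fast) * def
        d1_t <- d1e + (d1 - d1e) * exp(-tr / inac$tau_fast_ms)
        d2_t <- d2e + (d2 - d2e) * exp(-tr / inac$tau_slow_ms)
        avail_t <- 1 - d1_t - d2_t
        len <- segs$t1[i] - segs$t0[i]
        d1 <- d1e + (d1 - d1e) * exp(-len / inac$tau_fast_ms)
        d2 <- d2e + (d2 - d2e) * exp(-len / inac$tau_slow_ms)
      }
      trace[idx] <- gmax_uA_per_mV * a_t * avail_t * (v - erev) +
        g_leak_uA_per_mV * v
      a <- ae + (a - ae) * exp(-(segs$t1[i] - segs$t0[i]) / ta)
    }
    cur[, s] <- trace
  }
  if (noise_sd_uA > 0) {
    cur <- cur + matrix(stats::rnorm(length(cur), 0, noise_sd_uA), nrow = nrow(cur))
  }
  truth <- structure(
    list(kind = "ionic", model = model, gmax_uA_per_mV = gmax_uA_per_mV,
         act_tau_ms = act_tau_ms, inac = inac,
         g_leak_uA_per_mV = g_leak_uA_per_mV, noise_sd_uA = noise_sd_uA,
         erev_mV = erev, seed = seed, constants = k),
    class = "sim_truth"
  )
  sweep_set(protocol, cur, conditions = conditions,
            metadata = list(kind = "ionic", cell_id = cell_id,
                            label = label, seed = seed),
            truth = truth)
}

#' Simulate a cohort of cells
#'
#' Emulates the 4-8 oocytes behind each published curve: per-cell maximal
#' charge (or conductance) is scattered lognormally around the nominal
#' value, per-cell seeds are derived deterministically from the master
#' seed, and each cell is simulated independently. Normalization during
#' curve building removes the scale scatter, as it does for real
#' expression-level variability.
#'
#' @param type `"gating"` or `"ionic"`.
#' @param model the charge or conductance model passed to the per-cell
#'   simulator.
#' @param protocol a [make_protocol()] object.
#' @param n_cells number of cells.
#' @param scatter_sdlog sdlog of the lognormal per-cell scale factor
#'   (applied to `qmax_nC` / `gmax_uA_per_mV`); 0 means identical cells.
#' @param seed master integer seed.
#' @param label cohort label.
#' @param ... further arguments for [simulate_gating_sweeps()] or
#'   [simulate_ionic_sweeps()] (e.g. `qmax_nC`, `noise_sd_uA`, `tau_ms`,
#'   `conditions`).
#' @return A list of [sweep_set()] objects (one per cell) with attribute
#'   `"master_seed"`.
#' @export
simulate_cohort <- function(type = c("gating", "ionic"), model, protocol,
                            n_cells = 6, scatter_sdlog = 0.3, seed,
                            label = "", ...) {
  type <- match.arg(type)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_cells >= 1, scatter_sdlog >= 0)
  set.seed(seed)
  scales <- stats::rlnorm(n_cells, meanlog = 0, sdlog = scatter_sdlog)
  seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  dots <- list(...)
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    args <- dots
    if (type == "gating") {
      args$qmax_nC <- (args$qmax_nC %||% 2) * scales[i]
      fun <- simulate_gating_sweeps
    } else {
      args$gmax_uA_per_mV <- (args$gmax_uA_per_mV %||% 0.05) * scales[i]
      fun <- simulate_ionic_sweeps
    }
    args$model <- model
    args$protocol <- protocol
    args$seed <- seeds[i]
    args$cell_id <- sprintf("cell%02d", i)
    args$label <- label
    out[[i]] <- do.call(fun, args)
  }
  attr(out, "master_seed") <- seed
  out
}

#' Read and write sweep sets
#'
#' A sweep set is stored as two text files sharing a path prefix: a long
#' CSV (`<prefix>.csv` with columns `sweep`, `time_ms`, `voltage_mV`,
#' `current_uA`) and a JSON sidecar (`<prefix>.json`) holding the protocol,
#' ionic conditions, metadata and, for simulated sets, the generating
#' truth.
#'
#' @param ss a [sweep_set()].
#' @param prefix path prefix (without extension).
#' @return `write_sweep_set()`: the prefix, invisibly. `read_sweep_set()`:
#'   the reconstructed [sweep_set()].
#' @export
write_sweep_set <- function(ss, prefix) {
  stopifnot(inherits(ss, "sweep_set"))
  nsw <- ncol(ss$current_uA)
  long <- data.frame(
    sweep = rep(seq_len(nsw), each = nrow(ss$current_uA)),
    time_ms = rep(ss$time_ms, nsw),
    voltage_mV = as.vector(vapply(seq_len(nsw), function(s) voltage_trace(ss, s),
                                  numeric(length(ss$time_ms)))),
    current_uA = as.vector(ss$current_uA)
  )
  utils::write.csv(long, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(
    protocol = unclass_deep(ss$protocol),
    conditions = if (is.null(ss$conditions)) NULL else unclass_deep(ss$conditions),
    metadata = ss$metadata,
    truth = if (is.null(ss$truth)) NULL else serialize_truth(ss$truth)
  )
  jsonlite::write_json(side, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x) && !is.data.frame(x)) x <- lapply(x, unclass_deep)
  x
}

serialize_truth <- function(tr) {
  out <- unclass_deep(tr)
  out$model_class <- class(tr$model)[1]
  if (!is.null(tr$inac)) out$inac$params_class <- class(tr$inac$params)[1]
  if (is.function(out$tau_ms)) out$tau_ms <- NULL
  if (is.function(out$act_tau_ms)) out$act_tau_ms <- NULL
  out$constants <- NULL
  out
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(prefix) {
  long <- utils::read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pr <- side$protocol
  segs <- as.data.frame(pr$segments, stringsAsFactors = FALSE)
  proto <- structure(
    list(type = pr$type, holding_mV = pr$holding_mV, tail_mV = pr$tail_mV,
         segments = segs, sweeps = as.data.frame(pr$sweeps),
         sample_interval_ms = pr$sample_interval_ms),
    class = "voltage_protocol"
  )
  nsw <- nrow(proto$sweeps)
  cur <- matrix(long$current_uA, ncol = nsw)
  cond <- if (is.null(side$conditions)) NULL else {
    ionic_conditions(side$conditions$k_in_mM, side$conditions$k_out_mM,
                     side$conditions$temperature_K)
  }
  sweep_set(proto, cur, conditions = cond, metadata = side$metadata,
            truth = side$truth)
}
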