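#' Voltage-clamp pulse protocols
#'
#' Builds the two families of step protocols the analysis uses:
#'
#' * `"iv"`: an I-V / Q-V family. Each sweep holds at `holding_mV`, applies
#'   a hyperpolarized conditioning pre-pulse (to close all channels), steps
#'   to a test voltage drawn from a fixed-increment series, then returns to
#'   a tail voltage (where OFF gating charge is collected).
#' * `"inactivation"`: an availability family. Each sweep applies a long
#'   (default 19 s) conditioning step at a voltage from the series, followed
#'   by one fixed strong test pulse (default +60 mV) whose peak current
#'   reports the fraction of channels not inactivated.
#'
#' @param type `"iv"` or `"inactivation"`.
#' @param v_from,v_to,v_step voltage series in mV (test voltages for `"iv"`,
#'   conditioning voltages for `"inactivation"`), inclusive of `v_from` and,
#'   when on the grid, `v_to`.
#' @param holding_mV holding potential (default -100 for `"iv"`, -80 for
#'   `"inactivation"`).
#' @param baseline_ms pre-trace time spent at holding before the first step
#'   (used for baseline estimation).
#' @param prepulse_mV,prepulse_ms conditioning pre-pulse for `"iv"`.
#' @param step_ms duration of the variable step: the test step for `"iv"`,
#'   the conditioning step for `"inactivation"`.
#' @param test_mV,test_ms fixed test pulse for `"inactivation"`.
#' @param tail_mV,tail_ms post-step tail segment (default: back to the
#'   conditioning/pre-pulse voltage for `"iv"`, holding for
#'   `"inactivation"`).
#' @param sample_interval_ms sampling interval; defaults to 0.05 ms for
#'   `"iv"` and 1 ms for `"inactivation"` (desk-scale traces for 19 s
#'   pulses).
#' @return An object of class `voltage_protocol`: a list with the segment
#'   durations, the per-sweep table `sweeps` (`sweep`, `cond_mV`,
#'   `test_mV`), and `sample_interval_ms`.
#' @examples
#' p <- make_protocol("iv", v_from = -120, v_to = 60, v_step = 10)
#' nrow(p$sweeps) # 19
#' @export
make_protocol <- function(type = c("iv", "inactivation"),
                          v_from, v_to, v_step = 10,
                          holding_mV = NULL,
                          baseline_ms = 5,
                          prepulse_mV = -140, prepulse_ms = 50,
                          step_ms = NULL,
                          test_mV = 60, test_ms = 500,
                          tail_mV = NULL, tail_ms = 50,
                          sample_interval_ms = NULL) {
  type <- match.arg(type)
  if (missing(v_from) || missing(v_to)) {
    stop("`v_from` and `v_to` are required", call. = FALSE)
  }
  stopifnot(is.finite(v_from), is.finite(v_to), is.finite(v_step), v_step != 0)
  volts <- seq(v_from, v_to, by = v_step)
  if (length(volts) == 0L) stop("empty voltage step list", call. = FALSE)

  if (is.null(holding_mV)) holding_mV <- if (type == "iv") -100 else -80
  if (is.null(sample_interval_ms)) {
    sample_interval_ms <- if (type == "iv") 0.05 else 1
  }
  if (is.null(step_ms)) step_ms <- if (type == "iv") 50 else 19000

  if (type == "iv") {
    if (is.null(tail_mV)) tail_mV <- prepulse_mV
    segs <- data.frame(
      segment = c("baseline", "prepulse", "test", "tail"),
      duration_ms = c(baseline_ms, prepulse_ms, step_ms, tail_ms),
      stringsAsFactors = FALSE
    )
    sweeps <- data.frame(sweep = seq_along(volts), cond_mV = prepulse_mV,
                         test_mV = volts)
  } else {
    if (is.null(tail_mV)) tail_mV <- holding_mV
    segs <- data.frame(
      segment = c("baseline", "conditioning", "test", "tail"),
      duration_ms = c(baseline_ms, step_ms, test_ms, tail_ms),
      stringsAsFactors = FALSE
    )
    sweeps <- data.frame(sweep = seq_along(volts), cond_mV = volts,
                         test_mV = test_mV)
  }
  if (any(segs$duration_ms <= 0)) stop("segment durations must be > 0", call. = FALSE)
  stopifnot(sample_interval_ms > 0)
  # sampling must tile each segment to within one sample
  r <- segs$duration_ms / sample_interval_ms
  if (any(abs(r - round(r)) > 1e-6)) {
    stop("sample_interval_ms must divide every segment duration", call. = FALSE)
  }

  structure(
    list(type = type, holding_mV = holding_mV, tail_mV = tail_mV,
         segments = segs, sweeps = sweeps,
         sample_interval_ms = sample_interval_ms),
    class = "voltage_protocol"
  )
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol: %s>\n", x$type))
  cat(sprintf("  holding %g mV, %d sweeps, dt = %g ms\n",
              x$holding_mV, nrow(x$sweeps), x$sample_interval_ms))
  cat(sprintf("  segments: %s\n",
              paste(sprintf("%s (%g ms)", x$segments$segment,
                            x$segments$duration_ms), collapse = ", ")))
  vr <- range(if (x$type == "iv") x$sweeps$test_mV else x$sweeps$cond_mV)
  cat(sprintf("  variable step: %g .. %g mV\n", vr[1], vr[2]))
  invisible(x)
}

# Per-sweep segment table: voltage and [t0, t1) of each segment.
protocol_segments <- function(protocol, sweep) {
  sw <- protocol$sweeps[protocol$sweeps$sweep == sweep, ]
  if (nrow(sw) != 1L) stop("unknown sweep index", call. = FALSE)
  segs <- protocol$segments
  v <- vapply(segs$segment, function(s) {
    switch(s,
           baseline = protocol$holding_mV,
           prepulse = sw$cond_mV,
           conditioning = sw$cond_mV,
           test = sw$test_mV,
           tail = protocol$tail_mV)
  }, numeric(1))
  t1 <- cumsum(segs$duration_ms)
  data.frame(segment = segs$segment, voltage_mV = unname(v),
             t0 = c(0, t1[-length(t1)]), t1 = t1,
             stringsAsFactors = FALSE)
}

protocol_total_ms <- function(protocol) sum(protocol$segments$duration_ms)

protocol_times <- function(protocol) {
  seq(0, protocol_total_ms(protocol), by = protocol$sample_interval_ms)
}

#' Ionic conditions and the Nernst reversal potential
#'
#' `ionic_conditions()` records the potassium concentrations on either side
#' of the membrane; `nernst_mV()` returns the Nernst reversal potential
#' `E_rev = (RT/F) ln([K]out / [K]in)` in mV, the zero-current voltage of a
#' K-selective pore used as the driving-force reference in the conductance
#' calculation.
#'
#' @param k_in_mM,k_out_mM intracellular and extracellular K+ concentrations
#'   in mM; must be positive.
#' @param temperature_K temperature in kelvin.
#' @param cond an `ionic_conditions` object.
#' @param k a [gating_constants()] object (its temperature is used).
#' @return `nernst_mV()`: reversal potential in mV.
#' @examples
#' nernst_mV(ionic_conditions(k_in_mM = 120, k_out_mM = 12)) # ~ -57.8 mV
#' @export
ionic_conditions <- function(k_in_mM = 120, k_out_mM = 12,
                             temperature_K = 291.15) {
  stopifnot(is.finite(k_in_mM), k_in_mM > 0,
            is.finite(k_out_mM), k_out_mM > 0,
            is.finite(temperature_K), temperature_K > 0)
  structure(list(k_in_mM = k_in_mM, k_out_mM = k_out_mM,
                 temperature_K = temperature_K),
            class = "ionic_conditions")
}

#' @rdname ionic_conditions
#' @export
nernst_mV <- function(cond, k = gating_constants(temperature_K = cond$temperature_K)) {
  stopifnot(inherits(cond, "ionic_conditions"))
  k <- as_gating_constants(k)
  k$kT_mV * log(cond$k_out_mM / cond$k_in_mM)
}
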