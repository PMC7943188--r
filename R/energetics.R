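#' Free energy of a gating process from its Boltzmann parameters
#'
#' Converts a fitted valence/midpoint pair into the free energy of the
#' process, `G = z F V / 1000` kcal/mol (the factor 1000 converting mV to
#' V), with the standard error propagated from the fit errors of both
#' parameters: `se = (F/1000) sqrt((se_z V)^2 + (se_V z)^2)`.
#'
#' @param z apparent valence in e0.
#' @param v_mV midpoint voltage in mV.
#' @param se_z,se_v standard errors (0 when omitted).
#' @param k a [gating_constants()] object.
#' @param process label of the process (`"Q2"`, `"G"`, `"Inac"`, ...).
#' @param source `"fit"` or `"median"`.
#' @return An object of class `process_energy`: list with `G`, `se`
#'   (kcal/mol), `z`, `v_mV`, `process`, `source`.
#' @examples
#' process_energy(z = 13.6, v_mV = -44.29)$G # ~ -13.90 kcal/mol
#' @export
process_energy <- function(z, v_mV, se_z = 0, se_v = 0,
                           k = gating_constants(), process = "",
                           source = "fit") {
  k <- as_gating_constants(k)
  stopifnot(is.finite(z), is.finite(v_mV))
  if (is.na(se_z)) se_z <- 0
  if (is.na(se_v)) se_v <- 0
  G <- z * k$faraday_kcal * v_mV / 1000
  se <- k$faraday_kcal / 1000 * sqrt((se_z * v_mV)^2 + (se_v * z)^2)
  structure(list(G = G, se = se, z = z, v_mV = v_mV, process = process,
                 source = source),
            class = "process_energy")
}

#' @export
print.process_energy <- function(x, ...) {
  cat(sprintf("G%s = %.2f +/- %.2f kcal/mol (z = %.3g e0, V = %.4g mV, %s)\n",
              if (nzchar(x$process)) paste0("[", x$process, "]") else "",
              x$G, x$se, x$z, x$v_mV, x$source))
  invisible(x)
}

#' Energy shift of a process between a mutant and a reference channel
#'
#' `shift = G_mutant - G_reference`, with the two standard errors combined
#' in quadrature, flagged significant when `|shift|` reaches the threshold
#' (1 kcal/mol by convention for per-process energetics).
#'
#' @param mutant,reference [process_energy()] objects.
#' @param threshold significance threshold in kcal/mol.
#' @return An object of class `energy_shift`.
#' @export
energy_shift <- function(mutant, reference, threshold = 1.0) {
  stopifnot(inherits(mutant, "process_energy"),
            inherits(reference, "process_energy"))
  shift <- mutant$G - reference$G
  se <- sqrt(mutant$se^2 + reference$se^2)
  structure(list(G_mutant = mutant$G, G_reference = reference$G,
                 shift = shift, se = se, threshold = threshold,
                 significant = abs(shift) >= threshold,
                 process = mutant$process),
            class = "energy_shift")
}

#' @export
print.energy_shift <- function(x, ...) {
  cat(sprintf("shift%s = %+.2f +/- %.2f kcal/mol (%ssignificant at %.2g)\n",
              if (nzchar(x$process)) paste0("[", x$process, "]") else "",
              x$shift, x$se, if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}

#' Median voltage of charge movement
#'
#' The voltage that divides the area of the normalized Q-V curve into equal
#' halves: the area under the curve above `V_median` equals the area
#' between the curve and its upper asymptote below it. Equivalently, after
#' renormalizing the curve to span exactly 0 to 1, `V_median` is the upper
#' grid limit minus the trapezoidal integral of the curve, the point where
#' the cumulative area balance crosses zero (linear interpolation between
#' grid points is implicit in the trapezoid rule). `z F V_median` is the
#' total free energy of voltage-sensor activation (the generalized
#' interaction-energy estimator), so the curve must span both saturations:
#' by default the first normalized value must be at most 0.05 and the last
#' at least 0.95 of the range.
#'
#' Per-cell curves, when present, yield per-cell medians whose standard
#' error of the mean is reported; with a single curve the SE is 0.
#'
#' @param curve a `normalized_curve` (Q-V), or a data.frame with
#'   `voltage_mV` and `value`.
#' @param z_total total gating charge per channel in e0 assigned to this
#'   curve (13.6 for Shaker-type channels, the literature consensus).
#' @param saturation `c(low, high)` bounds for the saturation pre-check.
#' @return An object of class `median_charge`: `v_median_mV`, `se_mV`,
#'   `z_total`, `n_cells`, `percell_mV`.
#' @examples
#' k <- gating_constants()
#' v <- seq(-160, 0, 1)
#' q <- qv_two_state(two_state_params(2, -80), v, k)
#' median_voltage(as_normalized_curve(v, q))$v_median_mV # ~ -80
#' @export
median_voltage <- function(curve, z_total = 13.6, saturation = c(0.05, 0.95)) {
  if (is.data.frame(curve)) {
    curve <- as_normalized_curve(curve$voltage_mV, curve$value, kind = "QV")
  }
  stopifnot(inherits(curve, "normalized_curve"))
  med_one <- function(v, q, check = TRUE) {
    o <- order(v)
    v <- v[o]; q <- q[o]
    rng <- range(q)
    qn <- (q - rng[1]) / diff(rng)
    # saturation gate on the max-normalized scale (lower asymptote 0): the
    # observed range alone cannot reveal a truncated curve
    if (check &&
        (q[1] / rng[2] > saturation[1] + 1e-12 ||
         q[length(q)] < saturation[2] * rng[2] - 1e-12)) {
      stop("Q-V curve does not span both saturations; median voltage undefined",
           call. = FALSE)
    }
    vm <- v[length(v)] - pracma::trapz(v, qn)
    if (check && (vm < v[1] || vm > v[length(v)])) {
      stop("median voltage fell outside the measured span", call. = FALSE)
    }
    vm
  }
  v <- curve$voltage_mV
  vmed <- med_one(v, curve$mean)  # saturation gate applies to the mean curve
  percell <- curve$percell
  meds <- vapply(seq_len(ncol(percell)),
                 function(j) med_one(v, percell[, j], check = FALSE),
                 numeric(1))
  se <- if (length(meds) > 1) stats::sd(meds) / sqrt(length(meds)) else 0
  structure(list(v_median_mV = vmed, se_mV = se, z_total = z_total,
                 n_cells = curve$n_cells, percell_mV = meds),
            class = "median_charge")
}

#' Construct a median-charge record directly
#'
#' For median voltages obtained elsewhere (e.g. published tables).
#'
#' @param v_median_mV median voltage in mV.
#' @param se_mV its standard error.
#' @param z_total total gating charge in e0.
#' @return A `median_charge` object.
#' @export
median_charge <- function(v_median_mV, se_mV = 0, z_total = 13.6) {
  stopifnot(is.finite(v_median_mV), is.finite(se_mV), se_mV >= 0,
            is.finite(z_total), z_total > 0)
  structure(list(v_median_mV = v_median_mV, se_mV = se_mV, z_total = z_total,
                 n_cells = NA_integer_, percell_mV = numeric(0)),
            class = "median_charge")
}

#' @export
print.median_charge <- function(x, ...) {
  cat(sprintf("V_median = %.2f +/- %.2f mV (z_total = %.3g e0)\n",
              x$v_median_mV, x$se_mV, x$z_total))
  invisible(x)
}

#' Activation free energy from a median voltage
#'
#' The generalized interaction-energy estimate of the total free energy of
#' voltage-sensor activation: `G = z_total F V_median / 1000` kcal/mol,
#' with `se = z_total F se(V_median) / 1000`.
#'
#' @param m a [median_charge()] / [median_voltage()] result.
#' @param k a [gating_constants()] object.
#' @return A [process_energy()] with `source = "median"`.
#' @examples
#' gia_energy(median_charge(-48.54, 1.13))$G # ~ -15.24 kcal/mol
#' @export
gia_energy <- function(m, k = gating_constants()) {
  stopifnot(inherits(m, "median_charge"))
  process_energy(z = m$z_total, v_mV = m$v_median_mV, se_z = 0,
                 se_v = m$se_mV, k = k, process = "activation_total",
                 source = "median")
}

#' Thermodynamic mutant cycle on median-voltage free energies
#'
#' Quantifies the energetic coupling between two residues from the four
#' channels of a mutant cycle (parent, each single mutant, the double
#' mutant):
#' `ddG = (G_double - G_parent) - [(G_1 - G_parent) + (G_2 - G_parent)]`,
#' which for median-voltage energies with a shared total charge reduces to
#' `z F (V_double - V_1 - V_2 + V_parent) / 1000`. Additive mutations give
#' `ddG = 0`; `|ddG|` at or above the cutoff (1.8 kcal/mol, the
#' established criterion for this analysis) indicates the residues
#' interact. The uncertainty combines the four median-voltage standard
#' errors in quadrature and carries the same `z F` factor:
#' `se = z F sqrt(sum dV_i^2) / 1000`.
#'
#' @param wt,single1,single2,double [median_charge()] objects for the four
#'   channels; all must share the same `z_total`.
#' @param labels character(4) channel labels for reporting.
#' @param cutoff interaction cutoff in kcal/mol.
#' @param k a [gating_constants()] object.
#' @return An object of class `mutant_cycle_result`: the four
#'   [process_energy()] values, `ddG`, `se`, `cutoff`, `interacting`.
#' @export
mutant_cycle <- function(wt, single1, single2, double,
                         labels = c("parent", "single1", "single2", "double"),
                         cutoff = 1.8, k = gating_constants()) {
  chans <- list(wt, single1, single2, double)
  stopifnot(all(vapply(chans, inherits, logical(1), "median_charge")))
  zs <- vapply(chans, function(x) x$z_total, numeric(1))
  if (length(unique(zs)) != 1L) {
    stop("all four channels must share the same z_total", call. = FALSE)
  }
  k <- as_gating_constants(k)
  energies <- lapply(chans, gia_energy, k = k)
  names(energies) <- labels
  zF <- zs[1] * k$faraday_kcal / 1000
  ddG <- zF * (double$v_median_mV - single1$v_median_mV -
                 single2$v_median_mV + wt$v_median_mV)
  se <- zF * sqrt(sum(vapply(chans, function(x) x$se_mV, numeric(1))^2))
  structure(list(labels = labels, energies = energies,
                 v_median_mV = vapply(chans, function(x) x$v_median_mV, numeric(1)),
                 se_v_mV = vapply(chans, function(x) x$se_mV, numeric(1)),
                 ddG = ddG, se = se,
                 cutoff = cutoff, interacting = abs(ddG) >= cutoff,
                 z_total = zs[1]),
            class = "mutant_cycle_result")
}

#' @export
print.mutant_cycle_result <- function(x, ...) {
  cat("Thermodynamic mutant cycle (median-voltage free energies)\n")
  for (nm in x$labels) {
    e <- x$energies[[nm]]
    cat(sprintf("  %-24s V_median = %8.2f mV   G = %7.2f +/- %.2f kcal/mol\n",
                nm, e$v_mV, e$G, e$se))
  }
  cat(sprintf("  ddG = %+.2f +/- %.2f kcal/mol; cutoff %.2g -> %s\n",
              x$ddG, x$se, x$cutoff,
              if (x$interacting) "interacting" else "not interacting"))
  invisible(x)
}

#' Tabulate a mutant cycle result
#'
#' @param x a [mutant_cycle()] result.
#' @param ... unused.
#' @return A data.frame mirroring the published median-voltage tables
#'   (label, V_median, its SE, G, its SE).
#' @export
as.data.frame.mutant_cycle_result <- function(x, ...) {
  data.frame(
    label = x$labels,
    v_median_mV = x$v_median_mV,
    se_v_mV = x$se_v_mV,
    G_kcal = vapply(x$energies, function(e) e$G, numeric(1)),
    se_G_kcal = vapply(x$energies, function(e) e$se, numeric(1)),
    row.names = NULL
  )
}

#' Per-process energy shifts for a set of mutants
#'
#' Recomputes, from a table of fitted Boltzmann parameters, the shift in
#' process free energy of each mutant relative to a reference channel:
#' `G = z F V1/2` per channel and process, shifts `G_mutant - G_ref` with
#' quadrature-combined fit errors, flagged at the significance threshold.
#' The processes are the second (pore-opening-linked) charge transition of
#' the Q-V curve (`"Q2"`, using `z1`/`V1` of a three-state fit or the
#' two-state parameters where that model was used), conductance activation
#' (`"G"`) and slow inactivation (`"Inac"`).
#'
#' @param params a data.frame in the layout of [shaker_fit_table()].
#' @param process `"Q2"`, `"G"` or `"Inac"`.
#' @param reference label of the reference channel (for `"Q2"` the
#'   reference is usually the conduction-blocked background in which the
#'   gating currents were measured).
#' @param mutants labels to compare; default all rows with the needed
#'   parameters except the reference.
#' @param threshold significance threshold in kcal/mol.
#' @param k a [gating_constants()] object.
#' @return data.frame: `label`, `G_kcal`, `se_G`, `shift_kcal`, `se_shift`,
#'   `significant`.
#' @export
shift_report <- function(params, process = c("Q2", "G", "Inac"),
                         reference, mutants = NULL, threshold = 1.0,
                         k = gating_constants()) {
  process <- match.arg(process)
  cols <- switch(process,
    Q2 = c("qv_z1", "qv_v1", "se_qv_z1", "se_qv_v1"),
    G = c("gv_z", "gv_vhalf", "se_gv_z", "se_gv_vhalf"),
    Inac = c("inac_z", "inac_vhalf", "se_inac_z", "se_inac_vhalf"))
  energy_of <- function(row) {
    z <- row[[cols[1]]]; v <- row[[cols[2]]]
    sz <- row[[cols[3]]]; sv <- row[[cols[4]]]
    if (process == "Q2" && (!is.finite(z) || !is.finite(v))) {
      # fall back to the two-state Q-V parameters where that model was used
      z <- row[["qv2_z"]]; v <- row[["qv2_vhalf"]]
      sz <- row[["se_qv2_z"]]; sv <- row[["se_qv2_vhalf"]]
    }
    if (!is.finite(z) || !is.finite(v)) return(NULL)
    process_energy(z, v, ifelse(is.finite(sz), sz, 0),
                   ifelse(is.finite(sv), sv, 0), k = k, process = process)
  }
  ref_row <- params[params$mutant == reference, ]
  if (nrow(ref_row) != 1L) stop("reference channel not found", call. = FALSE)
  e_ref <- energy_of(ref_row)
  if (is.null(e_ref)) stop("reference lacks the needed parameters", call. = FALSE)
  if (is.null(mutants)) mutants <- setdiff(params$mutant, reference)
  rows <- lapply(mutants, function(lb) {
    r <- params[params$mutant == lb, ]
    if (nrow(r) != 1L) return(NULL)
    e <- energy_of(r)
    if (is.null(e)) return(NULL)
    sh <- energy_shift(e, e_ref, threshold)
    data.frame(label = lb, G_kcal = e$G, se_G = e$se, shift_kcal = sh$shift,
               se_shift = sh$se, significant = sh$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "process") <- process
  out
}
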