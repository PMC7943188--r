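#' Physical constants for gating energetics
#'
#' Bundles the temperature-dependent thermal voltage and the Faraday constant
#' used throughout the package. Voltages are handled in mV, energies in
#' kcal/mol; the mV-to-V conversion happens only inside the energy
#' calculations ([process_energy()], [gia_energy()], [mutant_cycle()]).
#'
#' The default Faraday constant is 96485 C/mol converted with 1 cal = 4.18 J
#' (F = 23.0825 kcal mol^-1 V^-1 per elementary charge), the rounded
#' conversion in common use in the channel-energetics literature; it
#' reproduces published median-voltage free-energy tables to their printed
#' precision. Pass `faraday_kcal = 96485/4184` for the thermochemical-calorie
#' value (23.061) if preferred. The default temperature 291.15 K corresponds
#' to the 17-18 degree C room temperature of cut-open oocyte recordings,
#' giving a thermal voltage RT/F of 25.09 mV.
#'
#' @param temperature_K absolute temperature in kelvin.
#' @param faraday_kcal Faraday constant in kcal mol^-1 V^-1 per elementary
#'   charge.
#' @return An object of class `gating_constants`: a list with elements
#'   `temperature_K`, `faraday_kcal`, `kT_mV` (thermal voltage RT/F in mV)
#'   and `F_over_RT` (its reciprocal, in mV^-1).
#' @examples
#' k <- gating_constants()
#' k$kT_mV # ~25.09 mV
#' @export
gating_constants <- function(temperature_K = 291.15, faraday_kcal = 96485 / 4180) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(faraday_kcal) || length(faraday_kcal) != 1L ||
      !is.finite(faraday_kcal) || faraday_kcal <= 0) {
    stop("`faraday_kcal` must be a single positive finite number", call. = FALSE)
  }
  R_J <- 8.31446       # J mol^-1 K^-1
  F_C <- 96485.332     # C mol^-1
  kT_mV <- 1000 * R_J * temperature_K / F_C
  structure(
    list(
      temperature_K = temperature_K,
      faraday_kcal = faraday_kcal,
      kT_mV = kT_mV,
      F_over_RT = 1 / kT_mV
    ),
    class = "gating_constants"
  )
}

#' @export
print.gating_constants <- function(x, ...) {
  cat("Gating constants:\n")
  cat(sprintf("  T        = %.2f K\n", x$temperature_K))
  cat(sprintf("  F        = %.4f kcal/mol/V per e0\n", x$faraday_kcal))
  cat(sprintf("  RT/F     = %.3f mV\n", x$kT_mV))
  invisible(x)
}

# Exponent clip: IEEE-754 safety at extreme voltages without touching
# accuracy anywhere near the physiological range.
clip_exp <- function(x, lim = 700) exp(pmin(pmax(x, -lim), lim))

as_gating_constants <- function(k) {
  if (inherits(k, "gating_constants")) return(k)
  stop("expected a `gating_constants` object (see gating_constants())", call. = FALSE)
}
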