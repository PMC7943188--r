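#' Packaged Shaker gating parameter tables
#'
#' Two small tables of published cut-open-oocyte voltage-clamp results for
#' Shaker-IR channels ship with the package so the energetics stages can be
#' exercised without recordings:
#'
#' * `shaker_fit_table()`: best-fit Boltzmann parameters (with fit standard
#'   errors) for the Q-V, G-V and Inac-V curves of the wild type and a
#'   panel of pore/sensor mutants. Q-V columns are split by the model used:
#'   `qv_v0/qv_z0/qv_v1/qv_z1` for channels fitted with the sequential
#'   three-state model, `qv2_vhalf/qv2_z` for channels whose shallow Q-V
#'   was fitted with the two-state Boltzmann.
#' * `shaker_median_table()`: median voltages of the normalized Q-V curves
#'   (mean +/- SEM across oocytes) for the V478W-background mutant cycle
#'   probing the S411-F433 interaction.
#'
#' @return A data.frame.
#' @export
shaker_fit_table <- function() {
  path <- system.file("extdata", "shaker_boltzmann_fits.csv",
                      package = "kvgating", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname shaker_fit_table
#' @export
shaker_median_table <- function() {
  path <- system.file("extdata", "shaker_qv_median_voltages.csv",
                      package = "kvgating", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
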