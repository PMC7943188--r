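#' Build a normalized, cohort-averaged curve
#'
#' Reduces a per-cell measurement table to the published curve format: each
#' cell's values are normalized by that cell's maximum (so expression-level
#' differences drop out), then the normalized values are averaged pointwise
#' across cells, with the standard error of the mean. Cells must cover a
#' common voltage grid; by default the grid is the intersection of the
#' per-cell grids (cells missing a shared point are dropped from that
#' point's average only if `grid = "complete"` excludes them entirely).
#'
#' @param measurements a data.frame with columns `cell_id`, `voltage_mV`
#'   and the value column for `kind` (see below), e.g. from
#'   [measure_cohort()]. A `normalized_curve` is returned unchanged
#'   (renormalization is idempotent).
#' @param kind `"QV"` (value column `Q_nC`), `"GV"` (`G_uA_per_mV`),
#'   `"InacV"` (`peak_uA`) or `"IV"` (`peak_uA`, not normalized).
#' @param value_col override the value column.
#' @param normalization `"max"` (divide by the per-cell maximum; default
#'   for QV/GV/InacV), `"maxabs"` or `"none"` (default for IV).
#' @param grid `"intersect"` (use voltages present in every cell) or
#'   `"complete"` (error unless all cells share the full grid).
#' @return An object of class `normalized_curve`: list with `kind`,
#'   `voltage_mV`, `percell` (voltage x cell matrix), `mean`, `sem`,
#'   `n_cells`.
#' @export
build_curve <- function(measurements,
                        kind = c("QV", "GV", "InacV", "IV"),
                        value_col = NULL, normalization = NULL,
                        grid = c("intersect", "complete")) {
  kind <- match.arg(kind)
  grid <- match.arg(grid)
  if (inherits(measurements, "normalized_curve")) return(measurements)
  if (is.null(value_col)) {
    value_col <- switch(kind, QV = "Q_nC", GV = "G_uA_per_mV",
                        InacV = "peak_uA", IV = "peak_uA")
  }
  if (is.null(normalization)) {
    normalization <- if (kind == "IV") "none" else "max"
  }
  stopifnot(all(c("cell_id", "voltage_mV", value_col) %in% names(measurements)))
  m <- measurements[is.finite(measurements[[value_col]]), ]
  cells <- unique(m$cell_id)
  if (length(cells) == 0L) stop("no cells with finite values", call. = FALSE)
  volts_by_cell <- lapply(cells, function(cl) sort(unique(m$voltage_mV[m$cell_id == cl])))
  shared <- Reduce(intersect, volts_by_cell)
  if (grid == "complete") {
    full <- sort(unique(m$voltage_mV))
    keep <- vapply(volts_by_cell, function(v) all(full %in% v), logical(1))
    if (!all(keep)) stop("cells do not cover the full voltage grid", call. = FALSE)
    shared <- full
  }
  shared <- sort(shared)
  if (length(shared) < 2L) stop("fewer than 2 shared voltages across cells", call. = FALSE)

  percell <- vapply(cells, function(cl) {
    sub <- m[m$cell_id == cl, ]
    v <- sub[[value_col]][match(shared, sub$voltage_mV)]
    switch(normalization,
           max = v / max(v),
           maxabs = v / max(abs(v)),
           none = v)
  }, numeric(length(shared)))
  percell <- matrix(percell, nrow = length(shared),
                    dimnames = list(NULL, cells))
  n <- length(cells)
  mu <- rowMeans(percell)
  sem <- if (n > 1) apply(percell, 1, stats::sd) / sqrt(n) else rep(0, length(shared))
  structure(
    list(kind = kind, voltage_mV = shared, percell = percell,
         mean = mu, sem = sem, n_cells = n,
         flags = if (n == 1) "n=1" else ""),
    class = "normalized_curve"
  )
}

#' Construct a normalized curve directly from values
#'
#' Convenience constructor for curves that already exist as
#' voltage-indexed values (e.g. model-generated data in tests, or digitized
#' mean curves).
#'
#' @param voltage_mV voltage grid.
#' @param values mean values, or a voltage x cell matrix.
#' @param kind curve kind (see [build_curve()]).
#' @param sem optional SEM vector (computed from `values` columns when a
#'   matrix is given).
#' @return A `normalized_curve`.
#' @export
as_normalized_curve <- function(voltage_mV, values, kind = "QV", sem = NULL) {
  if (is.matrix(values)) {
    n <- ncol(values)
    mu <- rowMeans(values)
    if (is.null(sem)) {
      sem <- if (n > 1) apply(values, 1, stats::sd) / sqrt(n) else rep(0, nrow(values))
    }
    percell <- values
  } else {
    n <- 1L
    mu <- values
    percell <- matrix(values, ncol = 1)
    if (is.null(sem)) sem <- rep(0, length(values))
  }
  stopifnot(length(voltage_mV) == length(mu), !is.unsorted(voltage_mV))
  structure(list(kind = kind, voltage_mV = as.numeric(voltage_mV),
                 percell = percell, mean = unname(as.numeric(mu)),
                 sem = unname(as.numeric(sem)), n_cells = n, flags = ""),
            class = "normalized_curve")
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve: %s, %d voltages (%g..%g mV), n = %d cells>\n",
              x$kind, length(x$voltage_mV), min(x$voltage_mV),
              max(x$voltage_mV), x$n_cells))
  invisible(x)
}

#' @export
plot.normalized_curve <- function(x, add = FALSE, col = 1, pch = 16, ...) {
  if (!add) {
    graphics::plot(x$voltage_mV, x$mean, col = col, pch = pch,
                   xlab = "Vm (mV)",
                   ylab = switch(x$kind, QV = "Q / Qmax", GV = "G / Gmax",
                                 InacV = "available fraction", IV = "I (uA)"),
                   ylim = range(c(x$mean - x$sem, x$mean + x$sem)), ...)
  } else {
    graphics::points(x$voltage_mV, x$mean, col = col, pch = pch, ...)
  }
  graphics::arrows(x$voltage_mV, x$mean - x$sem, x$voltage_mV, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.02, col = col)
  invisible(x)
}

#' Serialize / deserialize a normalized curve
#'
#' @param curve a `normalized_curve`.
#' @param path JSON file path.
#' @return `read_curve()` returns the curve.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "normalized_curve"))
  obj <- unclass(curve)
  obj$percell <- as.data.frame(obj$percell)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_normalized_curve(obj$voltage_mV, as.matrix(as.data.frame(obj$percell)),
                      kind = obj$kind, sem = obj$sem)
}
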