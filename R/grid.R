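# Planar modeling grid, precursor-pollutant registry, and gridded field
# containers shared by every stage of the pipeline.

#' Construct a planar modeling grid
#'
#' Defines a regular planar grid of square cells, indexed `(i, j)` with
#' `i = 1..n_rows` (row 1 is the southernmost row) and `j = 1..n_cols`
#' (column 1 is the westernmost column).  The origin is the planar coordinate
#' of the lower-left corner of cell `(1, 1)`, in km.  The grid is an abstract
#' equal-area plane: no geographic projection is attached.
#'
#' @param n_rows,n_cols Positive integers, grid dimensions.
#' @param cell_size_km Positive cell edge length in km (36 for a CMAQ-style
#'   continental-US grid).
#' @param origin_xy Length-2 numeric, planar `(x, y)` of the lower-left
#'   corner, km.
#' @return An object of class `model_grid`.
#' @examples
#' g <- model_grid(2, 3)
#' cell_center(g, 1, 1)  # (18, 18) km
#' @export
model_grid <- function(n_rows, n_cols, cell_size_km = 36, origin_xy = c(0, 0)) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1 ||
      n_rows != as.integer(n_rows))
    stop("'n_rows' must be a positive integer", call. = FALSE)
  if (!is.numeric(n_cols) || length(n_cols) != 1L || n_cols < 1 ||
      n_cols != as.integer(n_cols))
    stop("'n_cols' must be a positive integer", call. = FALSE)
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L ||
      !is.finite(cell_size_km) || cell_size_km <= 0)
    stop("'cell_size_km' must be a positive real", call. = FALSE)
  if (!is.numeric(origin_xy) || length(origin_xy) != 2L ||
      any(!is.finite(origin_xy)))
    stop("'origin_xy' must be two finite planar coordinates", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = as.numeric(cell_size_km),
         origin_xy = as.numeric(origin_xy)),
    class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  cat(sprintf("model_grid: %d x %d cells of %g km, origin (%g, %g) km\n",
              x$n_rows, x$n_cols, x$cell_size_km,
              x$origin_xy[1], x$origin_xy[2]))
  invisible(x)
}

#' Cell-center coordinates
#'
#' @param grid A [model_grid()].
#' @param i,j Row and column indices (vectorized, recycled).
#' @return A two-column matrix of planar `(x, y)` centers in km.
#' @export
cell_center <- function(grid, i, j) {
  stopifnot(inherits(grid, "model_grid"))
  if (any(i < 1 | i > grid$n_rows) || any(j < 1 | j > grid$n_cols))
    stop("cell index out of range", call. = FALSE)
  cbind(x = grid$origin_xy[1] + (j - 0.5) * grid$cell_size_km,
        y = grid$origin_xy[2] + (i - 0.5) * grid$cell_size_km)
}

#' All cell centers of a grid
#'
#' @param grid A [model_grid()].
#' @return List with matrices `x` and `y` of dimension `n_rows x n_cols`.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "model_grid"))
  i <- seq_len(grid$n_rows)
  j <- seq_len(grid$n_cols)
  list(
    x = matrix(grid$origin_xy[1] + (rep(j, each = grid$n_rows) - 0.5) *
                 grid$cell_size_km, grid$n_rows, grid$n_cols),
    y = matrix(grid$origin_xy[2] + (rep(i, times = grid$n_cols) - 0.5) *
                 grid$cell_size_km, grid$n_rows, grid$n_cols))
}

grids_equal <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size_km, b$cell_size_km)) &&
    isTRUE(all.equal(a$origin_xy, b$origin_xy))
}

# ---------------------------------------------------------------------------
# Precursor-pollutant pair registry

PRECURSORS <- c("PEC", "POC", "PSO4", "NOX", "SO2", "VOC")
POLLUTANTS <- c("PM25", "O3")
MONTHS     <- c("JAN", "JUL")
SECTORS    <- c("RC", "EGU")

#' Registry of valid precursor-pollutant pairs
#'
#' The pipeline models exactly eight emitted-precursor to ambient-pollutant
#' relationships: PEC, POC and PSO4 (primary PM2.5 precursors), NOX, SO2 and
#' VOC (secondary PM2.5 precursors) mapped to PM25, and NOX and VOC mapped to
#' O3.
#'
#' @return Data frame with columns `precursor` and `pollutant` (8 rows).
#' @export
pp_pairs <- function() {
  data.frame(
    precursor = c(PRECURSORS, "NOX", "VOC"),
    pollutant = c(rep("PM25", 6L), "O3", "O3"),
    stringsAsFactors = FALSE)
}

#' Construct a precursor-pollutant pair
#'
#' @param precursor One of `"PEC"`, `"POC"`, `"PSO4"`, `"NOX"`, `"SO2"`,
#'   `"VOC"`.
#' @param pollutant `"PM25"` or `"O3"`.
#' @return Object of class `pp_pair`.  Any combination outside the eight
#'   registered pairs is rejected.
#' @export
pp_pair <- function(precursor, pollutant) {
  reg <- pp_pairs()
  if (!any(reg$precursor == precursor & reg$pollutant == pollutant))
    stop(sprintf("invalid precursor-pollutant pair: %s -> %s",
                 precursor, pollutant), call. = FALSE)
  structure(list(precursor = precursor, pollutant = pollutant),
            class = "pp_pair")
}

#' @export
format.pp_pair <- function(x, ...) paste0(x$precursor, "_", x$pollutant)

#' @export
print.pp_pair <- function(x, ...) {
  cat(sprintf("pp_pair: %s -> %s\n", x$precursor, x$pollutant))
  invisible(x)
}

pair_key <- function(pair) paste0(pair$precursor, "_", pair$pollutant)

pair_from_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
  pp_pair(parts[1L], parts[2L])
}

pairs_equal <- function(a, b) {
  a$precursor == b$precursor && a$pollutant == b$pollutant
}

# ---------------------------------------------------------------------------
# Sensitivity fields

#' Construct a sensitivity field
#'
#' A sensitivity field holds the per-cell change in ambient pollutant
#' concentration attributable to a tagged source's precursor emissions, for
#' one run, month and precursor-pollutant pair.  Units are ug/m3 (monthly
#' mean of 24-hr averages) for PM25 pairs and ppb (monthly mean of daily
#' 8-hr maxima) for O3 pairs.  Negative values are permitted: winter
#' NOx-to-O3 sensitivities are negative under ozone titration.
#'
#' @param grid A [model_grid()].
#' @param values Numeric matrix `n_rows x n_cols` of finite values.
#' @param run_id Identifier of the run (or source) the field belongs to.
#' @param month `"JAN"` or `"JUL"`.
#' @param pair A [pp_pair()].
#' @return Object of class `sensitivity_field`.
#' @export
sensitivity_field <- function(grid, values, run_id, month, pair) {
  stopifnot(inherits(grid, "model_grid"), inherits(pair, "pp_pair"))
  if (!month %in% MONTHS)
    stop("'month' must be one of JAN, JUL", call. = FALSE)
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("field shape %d x %d does not match grid %d x %d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("field values must all be finite", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, run_id = as.character(run_id),
                 month = month, pair = pair),
            class = "sensitivity_field")
}

#' @export
print.sensitivity_field <- function(x, ...) {
  cat(sprintf("sensitivity_field %s [%s, %s]: %d x %d, range [%.4g, %.4g]\n",
              x$run_id, x$month, format(x$pair),
              x$grid$n_rows, x$grid$n_cols,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Element-wise sum of sensitivity fields
#'
#' First-order sensitivities superpose: the composite surface of a run group
#' is the element-wise sum of its members' surfaces.  All fields must share
#' the same grid, month and pair.
#'
#' @param fields A list of [sensitivity_field()] objects.
#' @param run_id Identifier for the summed field (defaults to the first
#'   field's `run_id`).
#' @return A [sensitivity_field()].
#' @export
sum_fields <- function(fields, run_id = NULL) {
  if (!length(fields)) stop("'fields' must be non-empty", call. = FALSE)
  stopifnot(all(vapply(fields, inherits, TRUE, "sensitivity_field")))
  f1 <- fields[[1L]]
  for (f in fields[-1L]) {
    if (!grids_equal(f$grid, f1$grid))
      stop("cannot sum fields on different grids", call. = FALSE)
    if (f$month != f1$month)
      stop("cannot sum fields for different months", call. = FALSE)
    if (!pairs_equal(f$pair, f1$pair))
      stop("cannot sum fields for different precursor-pollutant pairs",
           call. = FALSE)
  }
  vals <- Reduce(`+`, lapply(fields, `[[`, "values"))
  sensitivity_field(f1$grid, vals,
                    run_id = if (is.null(run_id)) f1$run_id else run_id,
                    month = f1$month, pair = f1$pair)
}

# ---------------------------------------------------------------------------
# Sources and run groups

#' Define an emitting source (one state and sector)
#'
#' @param state_id State identifier.
#' @param sector `"RC"` (residential combustion, ground-level area source) or
#'   `"EGU"` (electricity generating units, elevated point sources).
#' @param emissions Named list with elements `JAN` and `JUL`, each a named
#'   numeric vector of nonnegative tons per month keyed by precursor.
#' @param footprint Data frame with columns `i`, `j`, `weight`: the cells the
#'   source emits from and the (nonnegative) share of emissions per cell.
#'   Weights must sum to 1 within 1e-9.
#' @return Object of class `source_definition`.
#' @export
source_definition <- function(state_id, sector, emissions, footprint) {
  if (!sector %in% SECTORS)
    stop("'sector' must be RC or EGU", call. = FALSE)
  if (!is.list(emissions) || !all(MONTHS %in% names(emissions)))
    stop("'emissions' must be a list with JAN and JUL entries", call. = FALSE)
  for (m in MONTHS) {
    e <- emissions[[m]]
    if (length(e) && (is.null(names(e)) || any(!names(e) %in% PRECURSORS)))
      stop("emissions must be named by precursor", call. = FALSE)
    if (any(e < 0)) stop("emissions must be nonnegative", call. = FALSE)
  }
  footprint <- as.data.frame(footprint)
  if (!all(c("i", "j", "weight") %in% names(footprint)))
    stop("'footprint' needs columns i, j, weight", call. = FALSE)
  if (nrow(footprint) == 0L)
    stop("'footprint' must be non-empty", call. = FALSE)
  if (any(footprint$weight < 0))
    stop("footprint weights must be nonnegative", call. = FALSE)
  if (abs(sum(footprint$weight) - 1) > 1e-9)
    stop("footprint weights must sum to 1", call. = FALSE)
  structure(list(state_id = as.character(state_id), sector = sector,
                 emissions = emissions, footprint = footprint),
            class = "source_definition")
}

#' Group 1-3 same-sector sources into one model run
#'
#' Run groups mirror the practice of tagging several states in a single
#' sensitivity run; the composite surface is later separated back into
#' per-state regions by [region_grow()].
#'
#' @param run_id Run identifier.
#' @param sector `"RC"` or `"EGU"`; all members must share it.
#' @param members List of 1-3 [source_definition()] objects.
#' @return Object of class `run_group`.
#' @export
run_group <- function(run_id, sector, members) {
  if (!sector %in% SECTORS)
    stop("'sector' must be RC or EGU", call. = FALSE)
  if (length(members) < 1L || length(members) > 3L)
    stop("a run group holds 1 to 3 member states", call. = FALSE)
  stopifnot(all(vapply(members, inherits, TRUE, "source_definition")))
  if (any(vapply(members, `[[`, "", "sector") != sector))
    stop("all run-group members must share the sector", call. = FALSE)
  ids <- vapply(members, `[[`, "", "state_id")
  if (anyDuplicated(ids))
    stop("duplicate member states in run group", call. = FALSE)
  names(members) <- ids
  structure(list(run_id = as.character(run_id), sector = sector,
                 members = members),
            class = "run_group")
}
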