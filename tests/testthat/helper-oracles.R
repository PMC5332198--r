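# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (double loops, sort-and-interpolate) and never reuse package internals.

# Brute-force health-impact equation: explicit double loop over cells.
brute_impact <- function(field, exposure, beta) {
  s <- 0
  for (i in seq_len(nrow(field$values)))
    for (j in seq_len(ncol(field$values)))
      s <- s + exposure$y0[i, j] * beta * field$values[i, j] *
        exposure$pop[i, j]
  s
}

# Linear-interpolation percentile (quantile type 7), written from the
# definition: h = (n - 1) p + 1 over the sorted sample.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Dominant-contributor label oracle: BACKGROUND where the composite is below
# the floor, exact ground-truth |dx| ties OMITTED, otherwise the member with
# the largest ground-truth |dx|.
dominant_oracle <- function(ground_truth_fields, composite, floor) {
  states <- sort(names(ground_truth_fields))
  out <- matrix("BACKGROUND", nrow(composite$values), ncol(composite$values))
  above <- abs(composite$values) >= floor
  mags <- lapply(states, function(s) abs(ground_truth_fields[[s]]$values))
  for (idx in which(above)) {
    v <- vapply(mags, function(m) m[idx], numeric(1))
    top <- which(v == max(v))
    out[idx] <- if (length(top) > 1L) "OMITTED" else states[top]
  }
  out
}

# Arbitrary exposure surface built directly (no county stage) for oracle
# comparisons of the impact equation alone.
random_exposure <- function(grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    grid = grid,
    pop = matrix(runif(grid$n_rows * grid$n_cols, 0, 5e4),
                 grid$n_rows, grid$n_cols),
    y0 = matrix(runif(grid$n_rows * grid$n_cols, 0.005, 0.02),
                grid$n_rows, grid$n_cols)),
    class = "exposure_grid")
}

random_field <- function(grid, pair = pp_pair("SO2", "PM25"),
                         month = "JAN", run_id = "R", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sensitivity_field(
    grid, matrix(rnorm(grid$n_rows * grid$n_cols, 0, 0.5),
                 grid$n_rows, grid$n_cols),
    run_id = run_id, month = month, pair = pair)
}

# Two equal-sigma Gaussian-plume states on one grid, footprint centers
# `sep_cells` columns apart (even separations put the equidistant line on a
# cell column).  Returns members, per-state ground truth and the composite.
two_plume_case <- function(sep_cells = 8L, sigma_km = 72,
                           emissions = c(A = 1000, B = 1000),
                           n_rows = 30L, n_cols = 44L, center_row = 15L,
                           left_col = 14L, pair = pp_pair("POC", "PM25"),
                           month = "JAN", multiplier = 1) {
  grid <- model_grid(n_rows, n_cols)
  disp <- list(spread_km = sigma_km, offset_km = c(0, 0))
  mk <- function(id, col, tons) source_definition(
    id, "RC", emissions = list(JAN = c(POC = tons), JUL = c(POC = tons)),
    footprint = data.frame(i = center_row, j = col, weight = 1))
  srcs <- list(A = mk("A", left_col, emissions[["A"]]),
               B = mk("B", left_col + sep_cells, emissions[["B"]]))
  gt <- lapply(srcs, generate_plume, grid = grid, month = month, pair = pair,
               dispersion = disp, multiplier = multiplier)
  composite <- sum_fields(unname(gt), run_id = "RUN")
  list(grid = grid, sources = srcs, ground_truth = gt,
       composite = composite, dispersion = disp)
}

# One shared default-scenario fit per seed, reused across test files.
.fit_cache <- new.env(parent = emptyenv())
default_fit <- function(seed = 1L) {
  key <- paste0("seed", seed)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- source_burden(
      generate_scenario(default_scenario_config(seed = seed)))
  .fit_cache[[key]]
}
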