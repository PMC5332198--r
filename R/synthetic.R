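# Synthetic scenario generator.  Emulates per-source-state sensitivity
# surfaces from a tagged-sensitivity chemical-transport run with analytic
# Gaussian plumes, so the separation / exposure / impact stages can be
# exercised and validated against exact ground truth without an atmospheric
# model.

#' Default seasonal amplitude multipliers per (sector, pair)
#'
#' Scalar January / July multipliers applied to plume amplitude, encoding the
#' seasonal structure the pipeline must reproduce:
#' * residential combustion (RC) primary PM2.5 is strongly winter-dominant
#'   (20:1 January:July, matching a 20-fold January excess in deaths);
#' * EGU SO2-derived sulfate PM2.5 is summer-enhanced (July 5x January);
#' * NOx-to-O3 sensitivity is negative in January (ozone titration in cold,
#'   high-NOx conditions) and positive in July.
#'
#' @return Data frame with columns `sector`, `precursor`, `pollutant`,
#'   `jan`, `jul` (16 rows; every multiplier finite and nonzero).
#' @export
default_seasonal_profiles <- function() {
  reg <- pp_pairs()
  prof <- rbind(
    data.frame(sector = "RC", reg,
               jan = c(1.0, 1.0, 1.0, 1.0, 0.5, 1.0, -0.40, 0.30),
               jul = c(0.05, 0.05, 0.05, 0.5, 1.0, 0.5, 1.0, 1.0),
               stringsAsFactors = FALSE),
    data.frame(sector = "EGU", reg,
               jan = c(1.0, 1.0, 1.0, 0.8, 0.2, 0.8, -0.15, 0.30),
               jul = c(0.8, 0.8, 0.8, 1.0, 1.0, 1.0, 1.0, 1.0),
               stringsAsFactors = FALSE))
  rownames(prof) <- NULL
  prof
}

seasonal_multiplier <- function(profiles, sector, pair, month) {
  row <- profiles$sector == sector & profiles$precursor == pair$precursor &
    profiles$pollutant == pair$pollutant
  if (!any(row))
    stop(sprintf("no seasonal profile for %s %s", sector, format(pair)),
         call. = FALSE)
  if (month == "JAN") profiles$jan[row][1L] else profiles$jul[row][1L]
}

#' Generate a Gaussian-plume sensitivity field for one source
#'
#' The field is the superposition, over the source's footprint cells, of
#' isotropic Gaussian kernels centered at the footprint cell center displaced
#' by the advection offset:
#' \deqn{\Delta x(c) = E \, m \, a \sum_f w_f \exp(-d(c, f)^2 / 2\sigma^2)}
#' with `E` the precursor tons for the month, `m` the seasonal multiplier,
#' `a` the amplitude per ton, `w_f` the footprint weight and `d` the planar
#' distance between cell centers (km).  Amplitude is exactly linear in
#' emissions; a negative multiplier (winter NOx-to-O3 titration) flips the
#' whole field's sign.  The construction is deterministic; `seed` is accepted
#' for interface symmetry and only consumed if `noise_sd > 0`.
#'
#' @param source A [source_definition()].
#' @param grid A [model_grid()].
#' @param month `"JAN"` or `"JUL"`.
#' @param pair A [pp_pair()]; emissions are looked up by its precursor.
#' @param dispersion List with `spread_km` (Gaussian sigma, > 0) and
#'   `offset_km` (length-2 advection displacement, km).
#' @param multiplier Seasonal amplitude multiplier.
#' @param amplitude_per_ton Concentration units at a kernel center per ton of
#'   monthly emissions.
#' @param noise_sd Standard deviation of optional multiplicative log-normal
#'   roughness (0 keeps ground truth analytic; the default).
#' @param seed RNG seed, used only when `noise_sd > 0`.
#' @return A [sensitivity_field()] whose `run_id` is `"<state>_<sector>"`.
#' @export
generate_plume <- function(source, grid, month, pair, dispersion,
                           multiplier = 1, amplitude_per_ton = 1e-4,
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(source, "source_definition"),
            inherits(grid, "model_grid"), inherits(pair, "pp_pair"))
  sigma <- dispersion$spread_km
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
    stop("dispersion spread_km must be > 0", call. = FALSE)
  offset <- dispersion$offset_km
  if (is.null(offset)) offset <- c(0, 0)
  emis <- source$emissions[[month]]
  tons <- if (pair$precursor %in% names(emis)) emis[[pair$precursor]] else 0
  ctr <- cell_centers(grid)
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (tons > 0 && multiplier != 0) {
    fp <- source$footprint
    if (any(fp$i < 1 | fp$i > grid$n_rows | fp$j < 1 | fp$j > grid$n_cols))
      stop("footprint cell outside the grid", call. = FALSE)
    for (k in seq_len(nrow(fp))) {
      c0 <- cell_center(grid, fp$i[k], fp$j[k])
      d2 <- (ctr$x - (c0[1] + offset[1]))^2 + (ctr$y - (c0[2] + offset[2]))^2
      vals <- vals + fp$weight[k] * exp(-d2 / (2 * sigma^2))
    }
    vals <- vals * tons * multiplier * amplitude_per_ton
    if (noise_sd > 0) {
      if (!is.null(seed)) set.seed(seed)
      vals <- vals * exp(matrix(
        stats::rnorm(length(vals), 0, noise_sd), nrow(vals)))
    }
  }
  sensitivity_field(grid, vals,
                    run_id = paste(source$state_id, source$sector, sep = "_"),
                    month = month, pair = pair)
}

#' Generate a synthetic county table
#'
#' Tiles the grid's bounding rectangle with `n_counties` non-overlapping
#' rectangles covering the domain exactly, so areal-weighting conservation
#' can be tested in closed form.  Each county draws an adult (ages >= 25)
#' population log-uniformly from `pop_range` and ten yearly baseline
#' mortality rates uniformly from `mortality_range` (deaths per person per
#' year, a 2001-2010 analog).
#'
#' @param grid A [model_grid()].
#' @param n_counties Number of counties (>= 1).
#' @param pop_range Length-2 positive range for adult population.
#' @param mortality_range Length-2 nonnegative range for yearly rates.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return Data frame with columns `county_id`, `polygon` (WKT),
#'   `adult_population`, `rate_2001` .. `rate_2010`.
#' @export
generate_counties <- function(grid, n_counties = 48,
                              pop_range = c(5e3, 2e6),
                              mortality_range = c(0.008, 0.015),
                              seed = 1L) {
  stopifnot(inherits(grid, "model_grid"))
  if (n_counties < 1) stop("'n_counties' must be >= 1", call. = FALSE)
  if (length(pop_range) != 2L || any(pop_range <= 0) || diff(pop_range) < 0)
    stop("'pop_range' must be a positive non-empty range", call. = FALSE)
  if (length(mortality_range) != 2L || any(mortality_range < 0) ||
      diff(mortality_range) < 0)
    stop("'mortality_range' must be a nonnegative non-empty range",
         call. = FALSE)
  width  <- grid$n_cols * grid$cell_size_km
  height <- grid$n_rows * grid$cell_size_km
  x0 <- grid$origin_xy[1]; y0 <- grid$origin_xy[2]
  # near-square tiling: n_band bands of tiles, counts differing by <= 1
  n_band <- max(1L, floor(sqrt(n_counties)))
  base <- n_counties %/% n_band
  extra <- n_counties %% n_band
  per_band <- rep(base, n_band) + c(rep(1L, extra), rep(0L, n_band - extra))
  rects <- do.call(rbind, lapply(seq_len(n_band), function(b) {
    ylo <- y0 + (b - 1) * height / n_band
    yhi <- y0 + b * height / n_band
    k <- per_band[b]
    data.frame(xmin = x0 + (seq_len(k) - 1) * width / k,
               xmax = x0 + seq_len(k) * width / k,
               ymin = ylo, ymax = yhi)
  }))
  with_local_seed(seed, {
    n <- nrow(rects)
    pop <- exp(stats::runif(n, log(pop_range[1]), log(pop_range[2])))
    rates <- matrix(stats::runif(10L * n, mortality_range[1],
                                 mortality_range[2]), nrow = n, byrow = TRUE)
    colnames(rates) <- paste0("rate_", 2001:2010)
    out <- data.frame(
      county_id = sprintf("C%03d", seq_len(n)),
      polygon = mapply(rect_wkt, rects$xmin, rects$ymin, rects$xmax,
                       rects$ymax),
      adult_population = pop,
      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(rates))
  })
}

rect_wkt <- function(xmin, ymin, xmax, ymax) {
  sprintf("POLYGON ((%.17g %.17g, %.17g %.17g, %.17g %.17g, %.17g %.17g, %.17g %.17g))",
          xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax, xmin, ymin)
}

# Evaluate `expr` under a temporary RNG state so generators never perturb the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---------------------------------------------------------------------------
# Scenario configuration

#' Default synthetic scenario configuration
#'
#' Six synthetic states on a 40 x 60 grid of 36-km cells, paired into
#' two-state run groups per sector (three RC runs and three EGU runs).
#' Within a pair, footprint centers sit 9 cells (324 km) apart so the
#' broader EGU plumes (sigma 90 km) overlap appreciably while RC plumes
#' (sigma 54 km) overlap mildly -- the regime the separation stage is
#' designed for.  RC sources are 3 x 3 area footprints; EGUs are single-cell
#' point footprints.  Emissions differ across states by deterministic scale
#' factors so damage-function distributions are non-degenerate.
#'
#' @param seed Integer seed driving all scenario randomness (county table).
#' @param n_rows,n_cols,cell_size_km Grid specification.
#' @param sectors Which sectors to instantiate run groups for.
#' @param separation_cells Column separation between paired states'
#'   footprint centers.
#' @param n_counties,pop_range,mortality_range County-table parameters, see
#'   [generate_counties()].
#' @param seasonal Seasonal multiplier table
#'   (default [default_seasonal_profiles()]).
#' @param amplitude_per_ton Plume amplitude per ton of monthly emissions.
#' @return A `scenario_config` list accepted by [generate_scenario()].
#' @export
default_scenario_config <- function(seed = 1L, n_rows = 40L, n_cols = 60L,
                                    cell_size_km = 36,
                                    sectors = c("RC", "EGU"),
                                    separation_cells = 9L,
                                    n_counties = 48L,
                                    pop_range = c(5e3, 2e6),
                                    mortality_range = c(0.008, 0.015),
                                    seasonal = default_seasonal_profiles(),
                                    amplitude_per_ton = 1e-4) {
  n_states <- 6L
  group_rows <- as.integer(round(n_rows * c(0.225, 0.5, 0.775)))
  left_col <- as.integer(round(n_cols * 0.4))
  centers <- data.frame(
    state = sprintf("ST%d", seq_len(n_states)),
    i = rep(group_rows, each = 2L),
    j = rep(c(left_col, left_col + as.integer(separation_cells)), times = 3L))
  scale <- seq(0.7, 1.7, length.out = n_states)
  base_rc  <- c(PEC = 800, POC = 2500, PSO4 = 120, NOX = 1200, SO2 = 350,
                VOC = 2800)
  base_egu <- c(PEC = 250, POC = 120, PSO4 = 600, NOX = 9000, SO2 = 16000,
                VOC = 90)
  states <- lapply(seq_len(n_states), function(s) {
    list(state_id = centers$state[s], center_i = centers$i[s],
         center_j = centers$j[s],
         emissions = list(RC = base_rc * scale[s], EGU = base_egu * scale[s]))
  })
  names(states) <- centers$state
  groups <- list()
  for (sec in sectors)
    for (g in 1:3)
      groups[[length(groups) + 1L]] <- list(
        run_id = sprintf("%s_G%d", sec, g), sector = sec,
        states = centers$state[c(2L * g - 1L, 2L * g)])
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_km = cell_size_km, origin_xy = c(0, 0),
    states = states, run_groups = groups,
    dispersion = list(RC = list(spread_km = 54, offset_km = c(36, 18)),
                      EGU = list(spread_km = 90, offset_km = c(72, 36))),
    footprints = list(RC = "block3", EGU = "point"),
    seasonal = seasonal, amplitude_per_ton = amplitude_per_ton,
    n_counties = as.integer(n_counties), pop_range = pop_range,
    mortality_range = mortality_range, seed = as.integer(seed)),
    class = "scenario_config")
}

footprint_cells <- function(kind, ci, cj, n_rows, n_cols) {
  if (kind == "point") {
    data.frame(i = ci, j = cj, weight = 1)
  } else if (kind == "block3") {
    ij <- expand.grid(i = (ci - 1L):(ci + 1L), j = (cj - 1L):(cj + 1L))
    ij <- ij[ij$i >= 1 & ij$i <= n_rows & ij$j >= 1 & ij$j <= n_cols, ]
    data.frame(i = ij$i, j = ij$j, weight = rep(1 / nrow(ij), nrow(ij)))
  } else stop("unknown footprint kind: ", kind, call. = FALSE)
}

config_sources <- function(config) {
  lapply(config$states, function(st) {
    out <- list()
    for (sec in SECTORS) {
      emis <- st$emissions[[sec]]
      if (is.null(emis)) next
      fp <- footprint_cells(config$footprints[[sec]], st$center_i,
                            st$center_j, config$n_rows, config$n_cols)
      out[[sec]] <- source_definition(
        st$state_id, sec,
        emissions = list(JAN = emis, JUL = emis), footprint = fp)
    }
    out
  })
}

#' Generate a complete synthetic scenario
#'
#' Builds the grid, per-state sources, ground-truth plume fields for every
#' (state, sector, month, pair), composite run-group fields (exact
#' element-wise sums of member ground truths), the county table, and the
#' emissions table.  Regeneration from the same configuration and seed is
#' bit-identical.
#'
#' @param config A `scenario_config`, e.g. [default_scenario_config()].
#' @return Object of class `burden_scenario` with elements `grid`, `sources`,
#'   `run_groups`, `ground_truth`, `composites`, `counties`, `emissions`,
#'   `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- model_grid(config$n_rows, config$n_cols, config$cell_size_km,
                     config$origin_xy)
  sources <- config_sources(config)
  groups <- lapply(config$run_groups, function(g) {
    missing <- setdiff(g$states, names(sources))
    if (length(missing))
      stop("run group references undefined state(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    members <- lapply(g$states, function(s) {
      src <- sources[[s]][[g$sector]]
      if (is.null(src))
        stop(sprintf("state %s has no %s source", s, g$sector),
             call. = FALSE)
      src
    })
    run_group(g$run_id, g$sector, members)
  })
  names(groups) <- vapply(groups, `[[`, "", "run_id")

  reg <- pp_pairs()
  ground_truth <- list()
  for (s in names(sources)) for (sec in names(sources[[s]])) {
    src <- sources[[s]][[sec]]
    for (m in MONTHS) for (r in seq_len(nrow(reg))) {
      pair <- pp_pair(reg$precursor[r], reg$pollutant[r])
      mult <- seasonal_multiplier(config$seasonal, sec, pair, m)
      fld <- generate_plume(src, grid, m, pair, config$dispersion[[sec]],
                            multiplier = mult,
                            amplitude_per_ton = config$amplitude_per_ton)
      ground_truth[[s]][[sec]][[m]][[pair_key(pair)]] <- fld
    }
  }

  composites <- list()
  for (g in groups) for (m in MONTHS) for (r in seq_len(nrow(reg))) {
    pk <- paste0(reg$precursor[r], "_", reg$pollutant[r])
    members <- lapply(names(g$members), function(s)
      ground_truth[[s]][[g$sector]][[m]][[pk]])
    composites[[g$run_id]][[m]][[pk]] <- sum_fields(members,
                                                    run_id = g$run_id)
  }

  counties <- generate_counties(grid, config$n_counties, config$pop_range,
                                config$mortality_range, seed = config$seed)

  emissions <- do.call(rbind, lapply(names(sources), function(s)
    do.call(rbind, lapply(names(sources[[s]]), function(sec) {
      src <- sources[[s]][[sec]]
      do.call(rbind, lapply(MONTHS, function(m) {
        e <- src$emissions[[m]]
        data.frame(state = s, sector = sec, precursor = names(e), month = m,
                   tons = as.numeric(e), stringsAsFactors = FALSE)
      }))
    }))))
  rownames(emissions) <- NULL

  structure(list(grid = grid, sources = sources, run_groups = groups,
                 ground_truth = ground_truth, composites = composites,
                 counties = counties, emissions = emissions,
                 config = config),
            class = "burden_scenario")
}

#' @export
print.burden_scenario <- function(x, ...) {
  cat(sprintf(
    "burden_scenario: %d x %d grid, %d states, %d run groups, %d counties (seed %d)\n",
    x$grid$n_rows, x$grid$n_cols, length(x$sources), length(x$run_groups),
    nrow(x$counties), x$config$seed))
  invisible(x)
}

#' Monthly emissions for one state, sector, precursor
#'
#' @param scenario A `burden_scenario`.
#' @param state,sector,precursor,month Selection keys.
#' @return Tons per month (0 when absent).
#' @export
scenario_emissions <- function(scenario, state, sector, precursor, month) {
  e <- scenario$emissions
  row <- e$state == state & e$sector == sector &
    e$precursor == precursor & e$month == month
  if (!any(row)) 0 else sum(e$tons[row])
}

#' Nearest-footprint state territories
#'
#' Assigns every grid cell to the synthetic state whose footprint center is
#' nearest (a Voronoi partition).  Serves as the receptor-side "state
#' boundary" for within-source-state fractions; synthetic states have no
#' real geography.
#'
#' @param scenario A `burden_scenario`.
#' @return Named list of logical `n_rows x n_cols` masks, one per state.
#' @export
state_masks <- function(scenario) {
  cfg <- scenario$config
  ctr <- cell_centers(scenario$grid)
  states <- names(cfg$states)
  d2 <- lapply(states, function(s) {
    st <- cfg$states[[s]]
    c0 <- cell_center(scenario$grid, st$center_i, st$center_j)
    (ctr$x - c0[1])^2 + (ctr$y - c0[2])^2
  })
  nearest <- Reduce(function(a, b) pmin(a, b), d2)
  out <- lapply(seq_along(states), function(k) d2[[k]] <= nearest)
  # break exact ties in favor of the first state id in sort order
  taken <- matrix(FALSE, scenario$grid$n_rows, scenario$grid$n_cols)
  for (k in order(states)) {
    out[[k]] <- out[[k]] & !taken
    taken <- taken | out[[k]]
  }
  stats::setNames(out, states)
}
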