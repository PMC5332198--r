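# Areal-weighted gridding of county population and baseline mortality onto
# the modeling grid, under the uniform-density-within-county assumption.
# Polygon/cell intersection areas are computed by clipping the county polygon
# to each cell rectangle (Sutherland-Hodgman) and applying the shoelace
# formula; exact for the rectangular tilings the synthetic generator emits
# and correct for any simple polygon.

RATE_COLS <- paste0("rate_", 2001:2010)

#' Average a county's ten yearly baseline mortality rates
#'
#' Yearly rates are averaged for stability before any use downstream.
#'
#' @param rates Either a numeric vector of exactly 10 nonnegative yearly
#'   rates (deaths/person/year) or a one-row county record carrying columns
#'   `rate_2001` .. `rate_2010`.
#' @return The arithmetic mean rate.
#' @export
average_rates <- function(rates) {
  if (is.data.frame(rates) || is.list(rates)) {
    missing <- setdiff(RATE_COLS, names(rates))
    if (length(missing))
      stop("county record is missing rate column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    rates <- as.numeric(rates[RATE_COLS])
  }
  rates <- as.numeric(rates)
  if (length(rates) != 10L)
    stop("exactly 10 yearly rates are required", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("yearly rates must be finite and nonnegative", call. = FALSE)
  mean(rates)
}

# -- minimal planar polygon helpers -----------------------------------------

parse_wkt_polygon <- function(wkt) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
  body <- sub("\\)\\)\\s*$", "", body)
  pts <- strsplit(trimws(strsplit(body, ",", fixed = TRUE)[[1L]]), "\\s+")
  xy <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
  if (nrow(xy) < 4L || any(!is.finite(xy)))
    stop("malformed WKT polygon", call. = FALSE)
  # drop the closing vertex
  if (all(xy[1L, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  xy
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

# Clip a simple polygon to the axis-aligned rectangle
# [xmin, xmax] x [ymin, ymax] (Sutherland-Hodgman, rectangle edges in turn).
clip_to_rect <- function(xy, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (is.null(n) || n == 0L) return(pts)
    out <- vector("list", 2L * n)
    m <- 0L
    for (k in seq_len(n)) {
      cur <- pts[k, ]; prv <- pts[if (k == 1L) n else k - 1L, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) { m <- m + 1L; out[[m]] <- intersect(prv, cur) }
        m <- m + 1L; out[[m]] <- cur
      } else if (pin) {
        m <- m + 1L; out[[m]] <- intersect(prv, cur)
      }
    }
    if (m == 0L) matrix(numeric(0), 0L, 2L) else
      do.call(rbind, out[seq_len(m)])
  }
  ix <- function(p, q, t) p + (q - p) * t
  xy <- clip_edge(xy, function(p) p[1] >= xmin, function(p, q)
    ix(p, q, (xmin - p[1]) / (q[1] - p[1])))
  xy <- clip_edge(xy, function(p) p[1] <= xmax, function(p, q)
    ix(p, q, (xmax - p[1]) / (q[1] - p[1])))
  xy <- clip_edge(xy, function(p) p[2] >= ymin, function(p, q)
    ix(p, q, (ymin - p[2]) / (q[2] - p[2])))
  xy <- clip_edge(xy, function(p) p[2] <= ymax, function(p, q)
    ix(p, q, (ymax - p[2]) / (q[2] - p[2])))
  xy
}

#' Grid county populations and baseline mortality by areal weighting
#'
#' Each county's adult population is apportioned to cells in proportion to
#' the intersected area (uniform density); each cell's baseline mortality
#' rate is the population-weighted mean of the averaged yearly rates of its
#' contributing counties.  Cells with zero population carry a rate of 0 by
#' convention and contribute nothing downstream.
#'
#' @param counties County table: columns `county_id`, `polygon` (WKT,
#'   planar km), `adult_population`, `rate_2001` .. `rate_2010`.  Polygons
#'   must be pairwise non-overlapping.
#' @param grid A [model_grid()].
#' @return Object of class `exposure_grid` with matrices `pop` (persons) and
#'   `y0` (deaths/person/year).
#' @export
intersect_to_grid <- function(counties, grid) {
  stopifnot(inherits(grid, "model_grid"))
  counties <- as.data.frame(counties)
  need <- c("county_id", "polygon", "adult_population", RATE_COLS)
  missing <- setdiff(need, names(counties))
  if (length(missing))
    stop("county table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(counties$adult_population < 0))
    stop("adult_population must be nonnegative", call. = FALSE)
  cs <- grid$cell_size_km
  x0 <- grid$origin_xy[1]; y0g <- grid$origin_xy[2]
  xmax_dom <- x0 + grid$n_cols * cs
  ymax_dom <- y0g + grid$n_rows * cs
  pop  <- matrix(0, grid$n_rows, grid$n_cols)
  wsum <- matrix(0, grid$n_rows, grid$n_cols)  # rate-weighted population
  for (k in seq_len(nrow(counties))) {
    xy <- parse_wkt_polygon(counties$polygon[k])
    area <- shoelace_area(xy)
    if (area <= 0)
      stop(sprintf("county %s has non-positive polygon area",
                   counties$county_id[k]), call. = FALSE)
    rate <- average_rates(counties[k, ])
    bx <- range(xy[, 1L]); by <- range(xy[, 2L])
    if (bx[2] <= x0 || bx[1] >= xmax_dom || by[2] <= y0g ||
        by[1] >= ymax_dom) {
      message(sprintf("county %s lies outside the domain; skipped",
                      counties$county_id[k]))
      next
    }
    j_lo <- max(1L, floor((bx[1] - x0) / cs) + 1L)
    j_hi <- min(grid$n_cols, ceiling((bx[2] - x0) / cs))
    i_lo <- max(1L, floor((by[1] - y0g) / cs) + 1L)
    i_hi <- min(grid$n_rows, ceiling((by[2] - y0g) / cs))
    dens <- counties$adult_population[k] / area
    for (i in i_lo:i_hi) for (j in j_lo:j_hi) {
      a <- shoelace_area(clip_to_rect(
        xy, x0 + (j - 1) * cs, x0 + j * cs, y0g + (i - 1) * cs, y0g + i * cs))
      if (a > 0) {
        p <- dens * a
        pop[i, j] <- pop[i, j] + p
        wsum[i, j] <- wsum[i, j] + p * rate
      }
    }
  }
  y0 <- matrix(0, grid$n_rows, grid$n_cols)
  nz <- pop > 0
  y0[nz] <- wsum[nz] / pop[nz]
  structure(list(grid = grid, pop = pop, y0 = y0), class = "exposure_grid")
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf(
    "exposure_grid: %d x %d, total population %.4g, y0 range [%.4g, %.4g]\n",
    x$grid$n_rows, x$grid$n_cols, sum(x$pop), min(x$y0[x$pop > 0]),
    max(x$y0)))
  invisible(x)
}

#' Read / write a county table CSV
#'
#' Columns: `county_id`, `polygon` (WKT), `adult_population`,
#' `rate_2001` .. `rate_2010`.
#'
#' @param path CSV file path.
#' @param counties County data frame (for writing).
#' @return `read_counties` returns the data frame; `write_counties` returns
#'   `path` invisibly.
#' @export
read_counties <- function(path) {
  counties <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("county_id", "polygon", "adult_population", RATE_COLS),
                     names(counties))
  if (length(missing))
    stop("county CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  counties
}

#' @rdname read_counties
#' @export
write_counties <- function(counties, path) {
  utils::write.csv(counties, path, row.names = FALSE)
  invisible(path)
}
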