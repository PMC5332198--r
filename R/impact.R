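# The linear health-impact equation and its receptor-side accounting.
# Premature-mortality change for one field is
#   dy = sum_ij  y0_ij * beta * dx_ij * pop_ij
# with y0 the baseline mortality incidence rate, beta the
# concentration-response function, dx the sensitivity surface and pop the
# adult population of the cell.

#' Concentration-response function
#'
#' Fractional increase in baseline mortality per unit ambient concentration.
#' Defaults are the central epidemiological estimates used throughout: a 1%
#' mortality increase per 1 ug/m3 of annual-average PM2.5 (`beta = 0.01`),
#' and a 0.4% daily-mortality increase per 10 ppb of daily 8-hr maximum O3
#' (`beta = 0.0004` per ppb).
#'
#' @param pollutant `"PM25"` or `"O3"`.
#' @param beta Override for the fractional increase per concentration unit.
#' @param source_note Free-text provenance note.
#' @return Object of class `crf`.
#' @export
crf <- function(pollutant = c("PM25", "O3"), beta = NULL, source_note = "") {
  pollutant <- match.arg(pollutant)
  if (is.null(beta))
    beta <- if (pollutant == "PM25") 0.01 else 0.0004
  if (!is.finite(beta)) stop("'beta' must be finite", call. = FALSE)
  structure(list(pollutant = pollutant, beta = beta,
                 source_note = source_note), class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  unit <- if (x$pollutant == "PM25") "ug/m3" else "ppb"
  cat(sprintf("crf %s: %.4g per %s\n", x$pollutant, x$beta, unit))
  invisible(x)
}

#' Annual-rate mortality change for one sensitivity field
#'
#' Evaluates the health-impact equation over every grid cell, i.e. the
#' annual mortality change as if the month's mean concentration change
#' persisted all year.  The sign follows the field: an all-negative winter
#' NOx-to-O3 field yields a negative mortality change.
#'
#' @param field A [sensitivity_field()].
#' @param exposure An [intersect_to_grid()] exposure grid on the same grid.
#' @param crf A [crf()] matching the field's pollutant.
#' @return Deaths per year (signed).
#' @export
annualized_mortality <- function(field, exposure, crf) {
  stopifnot(inherits(field, "sensitivity_field"),
            inherits(exposure, "exposure_grid"), inherits(crf, "crf"))
  if (!grids_equal(field$grid, exposure$grid))
    stop("field and exposure grids do not match", call. = FALSE)
  if (crf$pollutant != field$pair$pollutant)
    stop(sprintf("CRF is for %s but the field's pollutant is %s",
                 crf$pollutant, field$pair$pollutant), call. = FALSE)
  sum(exposure$y0 * crf$beta * field$values * exposure$pop)
}

#' Half-year impact from an annual-rate impact
#'
#' January and July each stand in for six months of the year, so a month's
#' annual-rate impact contributes half of itself to the annual total.
#'
#' @param annual_rate_deaths Annual-rate deaths for one month's conditions.
#' @return `annual_rate_deaths / 2`.
#' @export
half_year_impact <- function(annual_rate_deaths) {
  stopifnot(is.finite(annual_rate_deaths))
  annual_rate_deaths / 2
}

#' Annual impact from two half-year impacts
#'
#' @param jan_half,jul_half Half-year impacts for January and July.
#' @return Their sum — equivalently the mean of the two annual-rate values.
#' @export
annual_impact <- function(jan_half, jul_half) {
  stopifnot(is.finite(jan_half), is.finite(jul_half))
  jan_half + jul_half
}

#' Within-source-state share of a field's impact
#'
#' Share (in percent) of a source's total mortality impact that falls inside
#' a receptor mask — typically the source state's own territory.  With
#' signed impacts the share can exceed 100% or be negative; a zero total is
#' reported as `NA` with attribute `"flagged"`.
#'
#' @param field A [sensitivity_field()].
#' @param exposure Matching exposure grid.
#' @param crf Matching [crf()].
#' @param state_cell_mask Logical matrix over the grid.
#' @return Percentage of total impact inside the mask.
#' @export
within_state_fraction <- function(field, exposure, crf, state_cell_mask) {
  stopifnot(is.logical(state_cell_mask))
  if (!all(dim(state_cell_mask) == dim(field$values)))
    stop("mask shape does not match the grid", call. = FALSE)
  impact <- exposure$y0 * crf$beta * field$values * exposure$pop
  total <- sum(impact)
  if (total == 0)
    return(structure(NA_real_, flagged = "zero total impact"))
  100 * sum(impact[state_cell_mask]) / total
}
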