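# Emissions-normalized health damage functions (deaths per 1,000 tons of
# precursor), low-emission outlier flagging, and descriptive summaries.

hdf_row <- function(source_state, sector, pair, period, value,
                    annual_emissions_tons, low_emission_flag) {
  data.frame(source_state = source_state, sector = sector,
             precursor = pair$precursor, pollutant = pair$pollutant,
             period = period, deaths_per_kton = value,
             annual_emissions_tons = annual_emissions_tons,
             low_emission_flag = low_emission_flag,
             stringsAsFactors = FALSE)
}

#' Monthly health damage function
#'
#' Normalizes a month's annual-rate mortality by the emissions that caused
#' it, annualized as monthly tons x 12: the damage function the month's
#' conditions would imply if they persisted all year, in deaths per 1,000
#' tons.  Zero emissions give an undefined (NA) value with the low-emission
#' flag set.
#'
#' @param annual_rate_deaths Annual-rate deaths under the month's
#'   conditions (signed).
#' @param monthly_emissions_tons Nonnegative precursor tons for the month.
#' @param source_state,sector,pair,period Identification for the output row
#'   (`period` is `"JAN"` or `"JUL"`).
#' @return One-row data frame with columns `source_state`, `sector`,
#'   `precursor`, `pollutant`, `period`, `deaths_per_kton`,
#'   `annual_emissions_tons`, `low_emission_flag`.
#' @export
monthly_hdf <- function(annual_rate_deaths, monthly_emissions_tons,
                        source_state = "?", sector = "RC",
                        pair = pp_pair("POC", "PM25"), period = "JAN") {
  stopifnot(is.finite(annual_rate_deaths))
  if (!is.finite(monthly_emissions_tons) || monthly_emissions_tons < 0)
    stop("'monthly_emissions_tons' must be nonnegative", call. = FALSE)
  annual_tons <- monthly_emissions_tons * 12
  if (annual_tons == 0)
    return(hdf_row(source_state, sector, pair, period, NA_real_, 0, TRUE))
  hdf_row(source_state, sector, pair, period,
          annual_rate_deaths / annual_tons * 1000, annual_tons, FALSE)
}

#' Annual health damage function from the two monthly ones
#'
#' The arithmetic mean of the January and July damage functions: mortality
#' risk per 1,000 tons under emissions spread uniformly across the year.
#' Values keep their sign, so negative January and positive July ozone
#' damage functions average through zero.  Flags are OR-ed.
#'
#' @param jan,jul One-row damage-function data frames from [monthly_hdf()]
#'   with matching state, sector and pair.
#' @return One-row damage-function data frame with `period = "ANNUAL"` and
#'   `annual_emissions_tons` the mean of the two monthly annualizations.
#' @export
annual_hdf <- function(jan, jul) {
  key <- c("source_state", "sector", "precursor", "pollutant")
  if (!identical(jan[1, key], jul[1, key]))
    stop("January and July damage functions must share state/sector/pair",
         call. = FALSE)
  hdf_row(jan$source_state, jan$sector,
          pp_pair(jan$precursor, jan$pollutant), "ANNUAL",
          mean(c(jan$deaths_per_kton, jul$deaths_per_kton)),
          mean(c(jan$annual_emissions_tons, jul$annual_emissions_tons)),
          jan$low_emission_flag || jul$low_emission_flag)
}

#' Flag low-emission outlier states
#'
#' Damage functions normalized by very small emissions are unreliable
#' (miniscule modeled impacts over miniscule tons inflate deaths-per-ton),
#' so two complementary rules flag them: per (sector, precursor, pollutant)
#' group, the `n_lowest` states with the smallest annual emissions (ties
#' broken by state id, clamped to the group size), and any state whose
#' annual emissions fall below an absolute floor.  With `per_pair = FALSE`
#' the rank rule uses each state's total emissions across pairs within the
#' sector.  Flags already present (e.g. zero emissions) are retained.
#' Flagged rows stay in the table; [summarize_burden()] excludes them from
#' percentiles.
#'
#' @param table Damage-function data frame (rows from [monthly_hdf()] /
#'   [annual_hdf()]).
#' @param n_lowest How many lowest-emitting states to flag per group.
#' @param floor_tons Absolute annual-emissions floor (tons/year).
#' @param per_pair Rank within each (sector, pair) group (default) or per
#'   sector overall.
#' @return The table with `low_emission_flag` updated.
#' @export
flag_low_emission <- function(table, n_lowest = 5, floor_tons = 1,
                              per_pair = TRUE) {
  if (!nrow(table)) stop("'table' must be non-empty", call. = FALSE)
  flag <- table$low_emission_flag
  flag <- flag | (table$annual_emissions_tons < floor_tons)
  if (per_pair) {
    groups <- split(seq_len(nrow(table)),
                    list(table$sector, table$precursor, table$pollutant,
                         table$period), drop = TRUE)
    for (idx in groups) {
      st <- table$source_state[idx]
      em <- table$annual_emissions_tons[idx]
      agg <- tapply(em, st, max)   # one emissions figure per state
      ord <- order(agg, names(agg))
      low <- names(agg)[ord][seq_len(min(n_lowest, length(agg)))]
      flag[idx] <- flag[idx] | st %in% low
    }
  } else {
    for (sec in unique(table$sector)) {
      idx <- which(table$sector == sec)
      tot <- tapply(table$annual_emissions_tons[idx],
                    table$source_state[idx], sum)
      ord <- order(tot, names(tot))
      low <- names(tot)[ord][seq_len(min(n_lowest, length(tot)))]
      flag[idx] <- flag[idx] | table$source_state[idx] %in% low
    }
  }
  table$low_emission_flag <- flag
  table
}

quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

#' Descriptive summary of impacts and damage functions
#'
#' Computes, per (sector, precursor, pollutant, period), the 5th percentile,
#' first quartile, median, third quartile and 95th percentile of damage
#' functions across states, excluding low-emission-flagged rows (linear
#' interpolation between order statistics, R quantile type 7); and per
#' state, the ratio of EGU to RC annual deaths (all pairs summed), with a
#' zero denominator reported as `NA`.
#'
#' @param impacts Impact data frame with columns `source_state`, `sector`,
#'   `precursor`, `pollutant`, `period`, `delta_deaths`.
#' @param hdfs Damage-function data frame (see [monthly_hdf()]).
#' @return Object of class `burden_summary`: data frames `hdf_percentiles`,
#'   `death_percentiles`, `sector_ratios`.
#' @export
summarize_burden <- function(impacts, hdfs) {
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  pct_names <- c("p5", "q1", "median", "q3", "p95")
  groups <- unique(hdfs[c("sector", "precursor", "pollutant", "period")])
  hdf_pct <- do.call(rbind, lapply(seq_len(nrow(groups)), function(r) {
    g <- groups[r, ]
    idx <- hdfs$sector == g$sector & hdfs$precursor == g$precursor &
      hdfs$pollutant == g$pollutant & hdfs$period == g$period &
      !hdfs$low_emission_flag
    vals <- hdfs$deaths_per_kton[idx]
    if (!length(vals)) {
      message(sprintf("no unflagged states for %s %s_%s %s",
                      g$sector, g$precursor, g$pollutant, g$period))
      q <- rep(NA_real_, 5L)
    } else q <- quantile7(vals, probs)
    cbind(g, stats::setNames(as.data.frame(as.list(q)), pct_names),
          n_states = length(vals))
  }))
  rownames(hdf_pct) <- NULL

  ann <- impacts[impacts$period == "ANNUAL", ]
  dgroups <- unique(ann[c("sector", "precursor", "pollutant")])
  death_pct <- do.call(rbind, lapply(seq_len(nrow(dgroups)), function(r) {
    g <- dgroups[r, ]
    vals <- ann$delta_deaths[ann$sector == g$sector &
                               ann$precursor == g$precursor &
                               ann$pollutant == g$pollutant]
    cbind(g, stats::setNames(as.data.frame(as.list(quantile7(vals, probs))),
                             pct_names), n_states = length(vals))
  }))
  rownames(death_pct) <- NULL

  states <- sort(unique(ann$source_state))
  tot <- function(sec, s) sum(ann$delta_deaths[ann$sector == sec &
                                                 ann$source_state == s])
  sector_ratios <- data.frame(
    source_state = states,
    rc_deaths = vapply(states, function(s) tot("RC", s), 0),
    egu_deaths = vapply(states, function(s) tot("EGU", s), 0),
    stringsAsFactors = FALSE)
  sector_ratios$egu_rc_ratio <- ifelse(
    sector_ratios$rc_deaths == 0, NA_real_,
    sector_ratios$egu_deaths / sector_ratios$rc_deaths)

  structure(list(hdf_percentiles = hdf_pct, death_percentiles = death_pct,
                 sector_ratios = sector_ratios),
            class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat("Damage-function percentiles (deaths per 1,000 tons, unflagged states):\n")
  print(x$hdf_percentiles, digits = 4)
  cat("\nEGU:RC annual death ratios by source state:\n")
  print(x$sector_ratios, digits = 4)
  invisible(x)
}
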