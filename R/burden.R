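# The fitting function: runs separation, exposure gridding, the impact
# equation and damage-function normalization over a synthetic scenario and
# returns a classed result object.

#' Fit source-attributed health burdens and damage functions
#'
#' Runs the full attribution analysis on a synthetic scenario: grids county
#' population and mortality by areal weighting, separates every composite
#' run-group sensitivity surface into per-state regions by seeded region
#' growing, applies the QA gate on the omitted impact share (with a
#' singleton ground-truth fallback for failing runs, mirroring re-running a
#' failing group one state at a time), evaluates the health-impact equation
#' per (state, sector, precursor-pollutant pair) and month, applies the
#' January/July half-year convention, and normalizes to health damage
#' functions with low-emission outlier flagging.
#'
#' @param scenario A [generate_scenario()] result.
#' @param crf_pm25,crf_o3 Concentration-response functions ([crf()]).
#' @param background_floor_rel Background floor for segmentation, as a
#'   fraction of each composite field's maximum `|dx|`.
#' @param omission_threshold QA pass threshold on the omitted impact share.
#' @param use_fallback Substitute singleton ground-truth fields for runs
#'   failing QA (the synthetic analog of isolated re-runs).
#' @param low_emission List of [flag_low_emission()] parameters
#'   (`n_lowest`, `floor_tons`, `per_pair`).
#' @return Object of class `source_burden` with elements `impacts`, `hdf`,
#'   `summary`, `qa`, `qa_reports`, `label_maps`, `exposure`, `scenario`,
#'   `params`, `call`.
#' @seealso [run_pipeline()] for the file-writing orchestration,
#'   [coef.source_burden()], [summary.source_burden()],
#'   [plot.source_burden()].
#' @examples
#' \donttest{
#' scen <- generate_scenario(default_scenario_config(seed = 1))
#' fit <- source_burden(scen)
#' print(fit)
#' head(coef(fit))
#' }
#' @export
source_burden <- function(scenario,
                          crf_pm25 = crf("PM25"),
                          crf_o3 = crf("O3"),
                          background_floor_rel = 1e-6,
                          omission_threshold = 0.10,
                          use_fallback = TRUE,
                          low_emission = list(n_lowest = 5, floor_tons = 1,
                                              per_pair = TRUE)) {
  stopifnot(inherits(scenario, "burden_scenario"),
            inherits(crf_pm25, "crf"), inherits(crf_o3, "crf"))
  cl <- match.call()
  exposure <- intersect_to_grid(scenario$counties, scenario$grid)
  crfs <- list(PM25 = crf_pm25, O3 = crf_o3)
  reg <- pp_pairs()
  masks <- state_masks(scenario)

  rates <- new.env(parent = emptyenv())   # key state|sector|pk|month -> rate
  in_rates <- new.env(parent = emptyenv())  # impact inside own-state mask
  add_rate <- function(env, state, sector, pk, month, value) {
    key <- paste(state, sector, pk, month, sep = "|")
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + value
  }
  get_rate <- function(env, state, sector, pk, month) {
    key <- paste(state, sector, pk, month, sep = "|")
    if (is.null(env[[key]])) 0 else env[[key]]
  }

  qa_rows <- list()
  qa_reports <- list()
  label_maps <- list()

  for (g in scenario$run_groups) for (m in MONTHS)
    for (r in seq_len(nrow(reg))) {
      pk <- paste0(reg$precursor[r], "_", reg$pollutant[r])
      composite <- scenario$composites[[g$run_id]][[m]][[pk]]
      crf_use <- crfs[[reg$pollutant[r]]]
      seeds <- select_seeds(composite, g$members)
      lm <- region_grow(composite, seeds,
                        background_floor =
                          background_floor_rel * max(abs(composite$values)))
      qa <- qa_run(lm, composite, exposure, crf_use,
                   omission_threshold = omission_threshold)
      fallback <- !qa$passed && use_fallback
      if (fallback) {
        fields <- lapply(names(g$members), function(s)
          scenario$ground_truth[[s]][[g$sector]][[m]][[pk]])
        names(fields) <- names(g$members)
      } else {
        fields <- split_run(composite, lm)
      }
      for (s in names(fields)) {
        dy <- annualized_mortality(fields[[s]], exposure, crf_use)
        add_rate(rates, s, g$sector, pk, m, dy)
        imp <- exposure$y0 * crf_use$beta * fields[[s]]$values * exposure$pop
        add_rate(in_rates, s, g$sector, pk, m, sum(imp[masks[[s]]]))
      }
      key <- paste(g$run_id, m, pk, sep = ".")
      label_maps[[key]] <- lm
      qa_reports[[key]] <- qa
      qa_rows[[key]] <- data.frame(
        run_id = g$run_id, sector = g$sector, month = m,
        precursor = reg$precursor[r], pollutant = reg$pollutant[r],
        omission_fraction = qa$omission_fraction, passed = qa$passed,
        degenerate = qa$degenerate, fallback = fallback,
        stringsAsFactors = FALSE)
    }
  qa_df <- do.call(rbind, qa_rows)
  rownames(qa_df) <- NULL

  impacts <- list()
  hdf <- list()
  for (s in sort(names(scenario$sources)))
    for (sec in names(scenario$sources[[s]]))
      for (r in seq_len(nrow(reg))) {
        pk <- paste0(reg$precursor[r], "_", reg$pollutant[r])
        pair <- pp_pair(reg$precursor[r], reg$pollutant[r])
        jan <- get_rate(rates, s, sec, pk, "JAN")
        jul <- get_rate(rates, s, sec, pk, "JUL")
        jan_in <- get_rate(in_rates, s, sec, pk, "JAN")
        jul_in <- get_rate(in_rates, s, sec, pk, "JUL")
        ann <- annual_impact(half_year_impact(jan), half_year_impact(jul))
        within <- if (jan + jul == 0) NA_real_ else
          100 * (jan_in + jul_in) / (jan + jul)
        base <- data.frame(source_state = s, sector = sec,
                           precursor = pair$precursor,
                           pollutant = pair$pollutant,
                           stringsAsFactors = FALSE)
        impacts[[paste(s, sec, pk, sep = "|")]] <- rbind(
          cbind(base, period = "JAN_HALF",
                delta_deaths = half_year_impact(jan),
                within_state_pct = NA_real_),
          cbind(base, period = "JUL_HALF",
                delta_deaths = half_year_impact(jul),
                within_state_pct = NA_real_),
          cbind(base, period = "ANNUAL", delta_deaths = ann,
                within_state_pct = within))
        tons_jan <- scenario_emissions(scenario, s, sec, pair$precursor,
                                       "JAN")
        tons_jul <- scenario_emissions(scenario, s, sec, pair$precursor,
                                       "JUL")
        h_jan <- monthly_hdf(jan, tons_jan, s, sec, pair, "JAN")
        h_jul <- monthly_hdf(jul, tons_jul, s, sec, pair, "JUL")
        hdf[[paste(s, sec, pk, sep = "|")]] <-
          rbind(h_jan, h_jul, annual_hdf(h_jan, h_jul))
      }
  impacts <- do.call(rbind, impacts)
  rownames(impacts) <- NULL
  hdf <- do.call(rbind, hdf)
  rownames(hdf) <- NULL
  hdf <- flag_low_emission(hdf,
                           n_lowest = low_emission$n_lowest %||% 5,
                           floor_tons = low_emission$floor_tons %||% 1,
                           per_pair = low_emission$per_pair %||% TRUE)
  summ <- summarize_burden(impacts, hdf)

  structure(list(
    impacts = impacts, hdf = hdf, summary = summ, qa = qa_df,
    qa_reports = qa_reports, label_maps = label_maps, exposure = exposure,
    scenario = scenario,
    params = list(crf_pm25 = crf_pm25, crf_o3 = crf_o3,
                  background_floor_rel = background_floor_rel,
                  omission_threshold = omission_threshold,
                  use_fallback = use_fallback,
                  low_emission = low_emission),
    call = cl), class = "source_burden")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.source_burden <- function(x, ...) {
  ann <- x$impacts[x$impacts$period == "ANNUAL", ]
  tot <- tapply(ann$delta_deaths, ann$sector, sum)
  cat("source_burden fit\n")
  cat(sprintf("  scenario: %d states, %d run groups, %d x %d grid (seed %d)\n",
              length(x$scenario$sources), length(x$scenario$run_groups),
              x$scenario$grid$n_rows, x$scenario$grid$n_cols,
              x$scenario$config$seed))
  cat(sprintf("  segmentation QA: %d/%d run-month-pair surfaces passed (max omission %.2f%%)\n",
              sum(x$qa$passed), nrow(x$qa),
              100 * max(x$qa$omission_fraction)))
  for (sec in names(tot))
    cat(sprintf("  %s annual premature deaths (all states, pairs): %.1f\n",
                sec, tot[[sec]]))
  invisible(x)
}

#' Summarize a source-burden fit
#'
#' @param object A `source_burden` fit.
#' @param ... Unused.
#' @return A `summary.source_burden` object: the descriptive summary tables
#'   plus the QA overview.
#' @export
summary.source_burden <- function(object, ...) {
  structure(list(summary = object$summary, qa = object$qa,
                 n_states = length(object$scenario$sources)),
            class = "summary.source_burden")
}

#' @export
print.summary.source_burden <- function(x, ...) {
  cat(sprintf("Segmentation QA (%d surfaces): max omission %.3f%%, %d fallback(s)\n\n",
              nrow(x$qa), 100 * max(x$qa$omission_fraction),
              sum(x$qa$fallback)))
  print(x$summary)
  invisible(x)
}

#' Annual damage functions as fit coefficients
#'
#' @param object A `source_burden` fit.
#' @param ... Unused.
#' @return Matrix of annual deaths per 1,000 tons: states in rows, one
#'   column per `sector.precursor.pollutant` combination.
#' @export
coef.source_burden <- function(object, ...) {
  ann <- object$hdf[object$hdf$period == "ANNUAL", ]
  states <- sort(unique(ann$source_state))
  cols <- unique(paste(ann$sector, ann$precursor, ann$pollutant, sep = "."))
  out <- matrix(NA_real_, length(states), length(cols),
                dimnames = list(states, cols))
  key <- paste(ann$sector, ann$precursor, ann$pollutant, sep = ".")
  for (r in seq_len(nrow(ann)))
    out[ann$source_state[r], key[r]] <- ann$deaths_per_kton[r]
  out
}

#' Diagnostic heat maps of a fit
#'
#' @param x A `source_burden` fit.
#' @param type `"labels"` (segmentation label map) or `"field"` (composite
#'   sensitivity surface).
#' @param run_id,month,pair_key Which surface to draw (defaults to the
#'   first run group, January, `"SO2_PM25"`).
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.source_burden <- function(x, type = c("labels", "field"),
                               run_id = NULL, month = "JAN",
                               pair_key = "SO2_PM25", ...) {
  type <- match.arg(type)
  if (is.null(run_id)) run_id <- x$scenario$run_groups[[1L]]$run_id
  key <- paste(run_id, month, pair_key, sep = ".")
  lm <- x$label_maps[[key]]
  if (is.null(lm))
    stop("no such surface: ", key, call. = FALSE)
  if (type == "labels") {
    z <- t(lm$labels)
    cols <- c("grey90", "grey30",
              grDevices::hcl.colors(length(lm$states), "Dark 2"))
    graphics::image(z, col = cols, axes = FALSE,
                    main = sprintf("labels %s", key), ...)
  } else {
    fld <- x$scenario$composites[[run_id]][[month]][[pair_key]]
    graphics::image(t(fld$values), col = grDevices::hcl.colors(64, "Blue-Red 3"),
                    axes = FALSE, main = sprintf("delta_x %s", key), ...)
  }
  invisible(x)
}
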