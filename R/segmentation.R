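# Separation of composite multi-state sensitivity surfaces into
# per-source-state regions by seeded best-first region growing, with
# deliberate omission of contested cells and a QA gate on the omitted share
# of health impact.

LBL_BACKGROUND <- 0L
LBL_OMITTED <- -1L

#' Select one seed cell per member state
#'
#' The seed for a state is the cell of maximum composite `|dx|` among cells
#' within the state's emission footprint dilated by one cell (8-neighbor
#' dilation), ties broken by smallest `(i, j)`.  If the field is identically
#' zero over the dilated footprint, the footprint's maximum-weight cell is
#' used and the state is flagged (attribute `"flagged"`), not rejected.
#'
#' @param field The composite [sensitivity_field()] of the run group.
#' @param members List of [source_definition()] members.
#' @return Named list `state_id -> c(i, j)`, with attribute `"flagged"`
#'   listing states whose footprint saw an all-zero field.
#' @export
select_seeds <- function(field, members) {
  stopifnot(inherits(field, "sensitivity_field"))
  a <- abs(field$values)
  nr <- field$grid$n_rows; nc <- field$grid$n_cols
  flagged <- character(0)
  seeds <- lapply(members, function(src) {
    fp <- src$footprint
    di <- rep(fp$i, each = 9L) + rep(-1:1, times = 3L)
    dj <- rep(fp$j, each = 9L) + rep(-1:1, each = 3L)
    keep <- di >= 1 & di <= nr & dj >= 1 & dj <= nc
    cells <- unique(cbind(di[keep], dj[keep]))
    vals <- a[cells]
    if (max(vals) == 0) {
      flagged <<- c(flagged, src$state_id)
      best <- fp[order(-fp$weight, fp$i, fp$j), ][1L, ]
      return(c(i = best$i, j = best$j))
    }
    cand <- cells[vals == max(vals), , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    c(i = cand[1L, 1L], j = cand[1L, 2L])
  })
  names(seeds) <- vapply(members, `[[`, "", "state_id")
  structure(seeds, flagged = flagged)
}

#' Grow per-state regions over a composite sensitivity field
#'
#' Best-first growth: one frontier entry per (cell, claiming region), with
#' priority the cell's composite `|dx|`.  The globally largest-`|dx|`
#' frontier cell is repeatedly popped (ties broken by smallest `(i, j)`) and
#' labeled with its claiming region; a cell that has been claimed by two or
#' more regions when popped is contested and labeled OMITTED, and never
#' seeds further growth.  Cells with `|dx|` below the background floor are
#' BACKGROUND.  Negative cells are claimable exactly like positive ones
#' (magnitude rule), so a winter titration field segments identically to its
#' positive mirror image.  Each state's region is 8-connected and contains
#' its seed; above-floor cells unreachable from any seed fall to BACKGROUND.
#'
#' @param field The composite [sensitivity_field()].
#' @param seeds Named list `state_id -> c(i, j)` as from [select_seeds()];
#'   seed cells must be distinct.
#' @param background_floor Absolute `|dx|` floor below which cells are
#'   background; default `1e-6 * max(|dx|)` keeps the floor scale-free.
#' @param connectivity 8 (default) or 4.
#' @return Object of class `label_map`: integer matrix `labels`
#'   (0 background, -1 omitted, k >= 1 the k-th entry of `states`), the
#'   sorted `states` vector, and the field's grid/run/month/pair metadata.
#' @export
region_grow <- function(field, seeds, background_floor = NULL,
                        connectivity = 8) {
  stopifnot(inherits(field, "sensitivity_field"))
  if (!connectivity %in% c(4, 8))
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  nr <- field$grid$n_rows; nc <- field$grid$n_cols
  a <- abs(field$values)
  if (is.null(background_floor)) background_floor <- 1e-6 * max(a)
  if (background_floor < 0)
    stop("'background_floor' must be >= 0", call. = FALSE)
  states <- sort(names(seeds))
  seed_lin <- vapply(states, function(s)
    (as.integer(seeds[[s]][2L]) - 1L) * nr + as.integer(seeds[[s]][1L]),
    integer(1))
  if (anyDuplicated(seed_lin))
    stop("seed cells must be distinct", call. = FALSE)

  labels <- matrix(NA_integer_, nr, nc)       # NA = not yet assigned
  claim  <- matrix(0L, nr, nc)                # 0 none, k region, -2 contested
  frontier <- matrix(FALSE, nr, nc)
  bg <- a < background_floor

  if (connectivity == 8) {
    off_i <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    off_j <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    off_i <- c(-1L, 1L, 0L, 0L)
    off_j <- c(0L, 0L, -1L, 1L)
  }

  push <- function(i, j, k) {
    ni <- i + off_i; nj <- j + off_j
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    for (t in which(ok)) {
      lin <- (nj[t] - 1L) * nr + ni[t]
      if (!is.na(labels[lin]) || bg[lin]) next
      cl <- claim[lin]
      if (cl == 0L) {
        claim[lin] <<- k
        frontier[lin] <<- TRUE
      } else if (cl != k && cl != -2L) {
        claim[lin] <<- -2L
      }
    }
  }

  for (k in seq_along(states)) {
    lin <- seed_lin[k]
    labels[lin] <- k
    frontier[lin] <- FALSE
  }
  for (k in seq_along(states)) {
    s <- seeds[[states[k]]]
    push(s[1L], s[2L], k)
  }

  repeat {
    fr <- which(frontier)
    if (!length(fr)) break
    v <- a[fr]
    cand <- fr[v == max(v)]
    if (length(cand) > 1L) {
      ci <- (cand - 1L) %% nr + 1L
      cj <- (cand - 1L) %/% nr + 1L
      cand <- cand[order(ci, cj)]
    }
    lin <- cand[1L]
    frontier[lin] <- FALSE
    if (!is.na(labels[lin])) next
    i <- (lin - 1L) %% nr + 1L
    j <- (lin - 1L) %/% nr + 1L
    if (claim[lin] == -2L) {
      labels[lin] <- LBL_OMITTED          # contested: deliberately omitted
    } else {
      k <- claim[lin]
      labels[lin] <- k
      push(i, j, k)
    }
  }
  labels[is.na(labels)] <- LBL_BACKGROUND

  structure(list(grid = field$grid, labels = labels, states = states,
                 run_id = field$run_id, month = field$month,
                 pair = field$pair, background_floor = background_floor),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  n_om <- sum(x$labels == LBL_OMITTED)
  n_bg <- sum(x$labels == LBL_BACKGROUND)
  cat(sprintf("label_map %s [%s, %s]: states %s; %d omitted, %d background cells\n",
              x$run_id, x$month, format(x$pair),
              paste(x$states, collapse = ", "), n_om, n_bg))
  invisible(x)
}

#' Character view of a label map
#'
#' @param label_map A `label_map`.
#' @return Character matrix over state ids, `"BACKGROUND"` and `"OMITTED"`.
#' @export
label_names <- function(label_map) {
  out <- matrix("BACKGROUND", nrow(label_map$labels), ncol(label_map$labels))
  out[label_map$labels == LBL_OMITTED] <- "OMITTED"
  for (k in seq_along(label_map$states))
    out[label_map$labels == k] <- label_map$states[k]
  out
}

#' Split a composite field into per-state attributed fields
#'
#' Each output field equals the composite on the state's labeled cells and 0
#' elsewhere; the per-state fields plus the OMITTED-masked and
#' BACKGROUND-masked fields re-sum to the composite exactly.
#'
#' @param field The composite [sensitivity_field()].
#' @param label_map Matching `label_map` (same run, month, pair).
#' @return Named list `state_id -> sensitivity_field`.
#' @export
split_run <- function(field, label_map) {
  stopifnot(inherits(field, "sensitivity_field"),
            inherits(label_map, "label_map"))
  if (field$run_id != label_map$run_id || field$month != label_map$month ||
      !pairs_equal(field$pair, label_map$pair))
    stop("label map metadata does not match the field", call. = FALSE)
  if (!grids_equal(field$grid, label_map$grid))
    stop("label map grid does not match the field", call. = FALSE)
  out <- lapply(seq_along(label_map$states), function(k) {
    v <- field$values
    v[label_map$labels != k] <- 0
    sensitivity_field(field$grid, v,
                      run_id = paste(field$run_id, label_map$states[k],
                                     sep = ":"),
                      month = field$month, pair = field$pair)
  })
  stats::setNames(out, label_map$states)
}

#' Mask a composite field to one label class
#'
#' @param field The composite [sensitivity_field()].
#' @param label_map Matching `label_map`.
#' @param label `"OMITTED"`, `"BACKGROUND"`, or a state id.
#' @return A [sensitivity_field()] equal to the composite on that class and
#'   0 elsewhere.
#' @export
masked_field <- function(field, label_map, label) {
  keep <- label_names(label_map) == label
  v <- field$values
  v[!keep] <- 0
  sensitivity_field(field$grid, v,
                    run_id = paste(field$run_id, label, sep = ":"),
                    month = field$month, pair = field$pair)
}

#' QA gate on the omitted share of health impact
#'
#' The omission fraction is the health-impact magnitude in OMITTED cells
#' over the magnitude in all non-BACKGROUND cells, with per-cell impact
#' magnitudes `|y0 * beta * dx * pop|` summed.  A run passes when the
#' fraction is below the threshold (default 10%); on failure the report
#' lists every member state for a singleton fallback re-run.
#'
#' @param label_map A `label_map`.
#' @param field The matching composite [sensitivity_field()].
#' @param exposure An [intersect_to_grid()] exposure grid on the same grid.
#' @param crf A [crf()] whose pollutant matches the field's pair.
#' @param omission_threshold Pass threshold on the omission fraction.
#' @return Object of class `qa_report`: `run_id`, `month`, `pair`,
#'   `omission_fraction`, `state_impact` (signed, per state), `passed`,
#'   `fallback_required`, `degenerate`.
#' @export
qa_run <- function(label_map, field, exposure, crf,
                   omission_threshold = 0.10) {
  stopifnot(inherits(label_map, "label_map"),
            inherits(exposure, "exposure_grid"), inherits(crf, "crf"))
  if (!grids_equal(exposure$grid, field$grid))
    stop("exposure grid does not match the field grid", call. = FALSE)
  if (crf$pollutant != field$pair$pollutant)
    stop("CRF pollutant does not match the field", call. = FALSE)
  impact <- exposure$y0 * crf$beta * field$values * exposure$pop
  non_bg <- label_map$labels != LBL_BACKGROUND
  total <- sum(abs(impact[non_bg]))
  omitted <- sum(abs(impact[label_map$labels == LBL_OMITTED]))
  degenerate <- total == 0
  omission_fraction <- if (degenerate) 0 else omitted / total
  state_impact <- vapply(seq_along(label_map$states), function(k)
    sum(impact[label_map$labels == k]), 0)
  names(state_impact) <- label_map$states
  passed <- omission_fraction < omission_threshold
  structure(list(
    run_id = label_map$run_id, month = label_map$month,
    pair = label_map$pair, omission_fraction = omission_fraction,
    state_impact = state_impact, passed = passed,
    fallback_required = if (passed) character(0) else label_map$states,
    degenerate = degenerate, omission_threshold = omission_threshold),
    class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("qa_report %s [%s, %s]: omission %.3f%% -> %s%s\n",
              x$run_id, x$month, format(x$pair),
              100 * x$omission_fraction,
              if (x$passed) "passed" else "FAILED (singleton fallback)",
              if (x$degenerate) " [degenerate: zero total impact]" else ""))
  invisible(x)
}

#' Write a QA report as JSON
#'
#' @param report A `qa_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  jsonlite::write_json(list(
    run_id = report$run_id, month = report$month,
    pair = format(report$pair),
    omission_fraction = report$omission_fraction,
    passed = report$passed,
    fallback_required = as.list(report$fallback_required),
    degenerate = report$degenerate), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a label map as an integer CSV raster with a JSON legend
#'
#' @param label_map A `label_map`.
#' @param path Raster CSV path; the legend is written alongside as
#'   `<path>.legend.json`.
#' @return `path`, invisibly (`read_label_map` returns the `label_map`).
#' @export
write_label_map <- function(label_map, path) {
  utils::write.table(label_map$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(
    run_id = label_map$run_id, month = label_map$month,
    pair = format(label_map$pair), states = as.list(label_map$states),
    background = LBL_BACKGROUND, omitted = LBL_OMITTED,
    background_floor = label_map$background_floor,
    n_rows = nrow(label_map$labels), n_cols = ncol(label_map$labels),
    cell_size_km = label_map$grid$cell_size_km),
    paste0(path, ".legend.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  leg <- jsonlite::read_json(paste0(path, ".legend.json"),
                             simplifyVector = TRUE)
  labels <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  grid <- model_grid(leg$n_rows, leg$n_cols, leg$cell_size_km)
  structure(list(grid = grid, labels = labels, states = leg$states,
                 run_id = leg$run_id, month = leg$month,
                 pair = pair_from_key(leg$pair),
                 background_floor = leg$background_floor),
            class = "label_map")
}
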