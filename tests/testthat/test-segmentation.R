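test_that("seeds sit on plume peaks with lexicographic tie-breaks", {
  case <- two_plume_case(sep_cells = 14L, sigma_km = 54)
  seeds <- select_seeds(case$composite, case$sources)
  # well-separated plumes: each seed at its own peak (exhaustive argmax)
  for (s in c("A", "B")) {
    m <- abs(case$ground_truth[[s]]$values)
    peak <- which(m == max(m), arr.ind = TRUE)
    expect_equal(unname(seeds[[s]]), unname(peak[1, ]))
  }

  # exact tie between two cells resolves to the smaller (i, j)
  g <- model_grid(5, 5)
  v <- matrix(0, 5, 5); v[2, 3] <- 1; v[4, 3] <- 1
  f <- sensitivity_field(g, v, "T", "JAN", pp_pair("POC", "PM25"))
  src <- source_definition("S", "RC",
                           list(JAN = c(POC = 1), JUL = c(POC = 1)),
                           data.frame(i = 3, j = 3, weight = 1))
  s <- select_seeds(f, list(src))
  expect_equal(unname(s$S), c(2, 3))

  # all-zero field over the footprint: flagged, seeded at max weight
  z <- sensitivity_field(g, matrix(0, 5, 5), "Z", "JAN",
                         pp_pair("POC", "PM25"))
  src2 <- source_definition("S", "RC",
                            list(JAN = c(POC = 1), JUL = c(POC = 1)),
                            data.frame(i = c(2, 4), j = c(2, 4),
                                       weight = c(0.3, 0.7)))
  s2 <- select_seeds(z, list(src2))
  expect_equal(unname(s2$S), c(4, 4))
  expect_identical(attr(s2, "flagged"), "S")
})

test_that("a single connected plume is fully claimed with zero omission", {
  case <- two_plume_case(sep_cells = 8L)
  f <- case$ground_truth$A
  f <- sensitivity_field(f$grid, f$values, "RUN", "JAN", f$pair)
  seeds <- select_seeds(f, case$sources["A"])
  lm <- region_grow(f, seeds["A"])
  nm <- label_names(lm)
  above <- abs(f$values) >= lm$background_floor
  expect_true(all(nm[above] == "A"))
  expect_true(all(nm[!above] == "BACKGROUND"))
  expect_equal(sum(nm == "OMITTED"), 0L)
})

test_that("disjoint plumes match the dominant-contributor oracle exactly", {
  # separation far beyond the above-floor radius at a permissive floor
  case <- two_plume_case(sep_cells = 24L, sigma_km = 40, n_cols = 60L)
  floor <- 1e-3 * max(abs(case$composite$values))
  seeds <- select_seeds(case$composite, case$sources)
  lm <- region_grow(case$composite, seeds, background_floor = floor)
  oracle <- dominant_oracle(case$ground_truth, case$composite, floor)
  expect_identical(label_names(lm), oracle)
  expect_equal(sum(lm$labels == -1L), 0L)
})

test_that("an all-negative field segments like its positive mirror", {
  case_pos <- two_plume_case(pair = pp_pair("NOX", "O3"), multiplier = 1)
  case_neg <- two_plume_case(pair = pp_pair("NOX", "O3"), multiplier = -1)
  expect_identical(case_neg$composite$values, -case_pos$composite$values)
  lm_pos <- region_grow(case_pos$composite,
                        select_seeds(case_pos$composite, case_pos$sources))
  lm_neg <- region_grow(case_neg$composite,
                        select_seeds(case_neg$composite, case_neg$sources))
  expect_identical(lm_pos$labels, lm_neg$labels)
})

test_that("label maps are invariant to member-list permutation", {
  case <- two_plume_case(sep_cells = 6L, sigma_km = 72)
  s1 <- select_seeds(case$composite, case$sources)
  s2 <- select_seeds(case$composite, rev(case$sources))
  lm1 <- region_grow(case$composite, s1)
  lm2 <- region_grow(case$composite, s2)
  expect_identical(lm1$labels, lm2$labels)
  expect_identical(lm1$states, lm2$states)
})

test_that("regions are 8-connected and contain their seeds", {
  case <- two_plume_case(sep_cells = 8L)
  seeds <- select_seeds(case$composite, case$sources)
  lm <- region_grow(case$composite, seeds)
  for (k in seq_along(lm$states)) {
    cells <- which(lm$labels == k, arr.ind = TRUE)
    seed <- seeds[[lm$states[k]]]
    expect_true(any(cells[, 1] == seed[1] & cells[, 2] == seed[2]))
    # flood fill from the seed over the region must reach every cell
    reach <- matrix(FALSE, nrow(lm$labels), ncol(lm$labels))
    reach[seed[1], seed[2]] <- TRUE
    repeat {
      grew <- FALSE
      idx <- which(reach, arr.ind = TRUE)
      for (r in seq_len(nrow(idx)))
        for (di in -1:1) for (dj in -1:1) {
          i <- idx[r, 1] + di; j <- idx[r, 2] + dj
          if (i >= 1 && i <= nrow(reach) && j >= 1 && j <= ncol(reach) &&
              !reach[i, j] && lm$labels[i, j] == k) {
            reach[i, j] <- TRUE; grew <- TRUE
          }
        }
      if (!grew) break
    }
    expect_equal(sum(reach), nrow(cells))
  }
  expect_error(region_grow(case$composite,
                           list(A = c(15, 14), B = c(15, 14))), "distinct")
})

test_that("split_run is an exact masking partition of the composite", {
  case <- two_plume_case(sep_cells = 8L)
  lm <- region_grow(case$composite,
                    select_seeds(case$composite, case$sources))
  parts <- split_run(case$composite, lm)
  resum <- parts$A$values + parts$B$values +
    masked_field(case$composite, lm, "OMITTED")$values +
    masked_field(case$composite, lm, "BACKGROUND")$values
  expect_equal(resum, case$composite$values, tolerance = 1e-12)
  # singleton run: the only state receives every non-background cell
  single <- case$ground_truth$A
  single <- sensitivity_field(single$grid, single$values, "RUN", "JAN",
                              single$pair)
  lm1 <- region_grow(single, select_seeds(single, case$sources["A"]))
  p1 <- split_run(single, lm1)
  nb <- label_names(lm1) != "BACKGROUND"
  expect_equal(p1$A$values[nb], single$values[nb])

  bad <- sensitivity_field(case$grid, case$composite$values, "OTHER", "JAN",
                           case$composite$pair)
  expect_error(split_run(bad, lm), "metadata")
})

test_that("QA accounting covers empty, full and degenerate omission", {
  case <- two_plume_case(sep_cells = 8L)
  exposure <- intersect_to_grid(generate_counties(case$grid, 12, seed = 3),
                                case$grid)
  pm <- crf("PM25")
  lm <- region_grow(case$composite,
                    select_seeds(case$composite, case$sources))
  qa <- qa_run(lm, case$composite, exposure, pm)
  expect_true(qa$omission_fraction >= 0 && qa$omission_fraction < 1)
  expect_length(qa$fallback_required, 0)

  # hand-built maps exercise the boundary cases
  no_omit <- lm; no_omit$labels[no_omit$labels == -1L] <- 1L
  qa0 <- qa_run(no_omit, case$composite, exposure, pm)
  expect_equal(qa0$omission_fraction, 0)
  expect_true(qa0$passed)

  all_omit <- lm; all_omit$labels[all_omit$labels > 0L] <- -1L
  qa1 <- qa_run(all_omit, case$composite, exposure, pm)
  expect_equal(qa1$omission_fraction, 1)
  expect_false(qa1$passed)
  expect_identical(qa1$fallback_required, all_omit$states)

  zero <- sensitivity_field(case$grid,
                            matrix(0, case$grid$n_rows, case$grid$n_cols),
                            "RUN", "JAN", case$composite$pair)
  qaz <- qa_run(lm, zero, exposure, pm)
  expect_true(qaz$degenerate)
  expect_equal(qaz$omission_fraction, 0)
})

test_that("widening plume separation never increases the omitted share", {
  grid_cells <- 60L
  exposure <- NULL
  fracs <- vapply(c(6L, 8L, 10L, 12L), function(sep) {
    case <- two_plume_case(sep_cells = sep, sigma_km = 72,
                           n_cols = grid_cells)
    if (is.null(exposure))
      exposure <<- intersect_to_grid(
        generate_counties(case$grid, 20, seed = 7), case$grid)
    lm <- region_grow(case$composite,
                      select_seeds(case$composite, case$sources))
    qa_run(lm, case$composite, exposure, crf("PM25"))$omission_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("label maps round-trip through the CSV raster + legend", {
  case <- two_plume_case(sep_cells = 8L)
  lm <- region_grow(case$composite,
                    select_seeds(case$composite, case$sources))
  path <- withr::local_tempfile(fileext = ".csv")
  write_label_map(lm, path)
  lm2 <- read_label_map(path)
  expect_identical(lm2$labels, lm$labels)
  expect_identical(lm2$states, lm$states)
  expect_identical(lm2$run_id, lm$run_id)
})
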