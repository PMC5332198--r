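test_that("grid geometry maps cells to planar rectangles", {
  g <- model_grid(2, 3, 36, c(0, 0))
  expect_equal(g$n_rows * g$n_cols, 6L)
  expect_equal(as.numeric(cell_center(g, 1, 1)), c(18, 18))
  expect_equal(as.numeric(cell_center(g, 2, 3)), c(90, 54))
  ctr <- cell_centers(g)
  expect_equal(ctr$x[1, 1], 18)
  expect_equal(ctr$y[2, 3], 54)

  g1 <- model_grid(1, 1, 36)
  expect_equal(as.numeric(cell_center(g1, 1, 1)), c(18, 18))

  expect_error(model_grid(0, 3, 36), "n_rows")
  expect_error(model_grid(3, -1, 36), "n_cols")
  expect_error(model_grid(3, 3, 0), "cell_size_km")
})

test_that("pair registry is closed over exactly eight combinations", {
  reg <- pp_pairs()
  expect_equal(nrow(reg), 8L)
  for (r in seq_len(nrow(reg)))
    expect_s3_class(pp_pair(reg$precursor[r], reg$pollutant[r]), "pp_pair")
  for (bad in c("PEC", "POC", "PSO4", "SO2"))
    expect_error(pp_pair(bad, "O3"), "invalid precursor-pollutant pair")
  expect_error(pp_pair("NH3", "PM25"), "invalid")
})

test_that("sensitivity fields validate shape, finiteness and month", {
  g <- model_grid(3, 4)
  v <- matrix(0, 3, 4)
  f <- sensitivity_field(g, v, "R1", "JAN", pp_pair("NOX", "O3"))
  expect_s3_class(f, "sensitivity_field")
  expect_error(sensitivity_field(g, matrix(0, 4, 3), "R1", "JAN",
                                 pp_pair("NOX", "O3")), "shape")
  v[2, 2] <- NA
  expect_error(sensitivity_field(g, v, "R1", "JAN", pp_pair("NOX", "O3")),
               "finite")
  expect_error(sensitivity_field(g, matrix(0, 3, 4), "R1", "FEB",
                                 pp_pair("NOX", "O3")), "month")
  # negative values are legitimate (winter titration)
  expect_silent(sensitivity_field(g, matrix(-1, 3, 4), "R1", "JAN",
                                  pp_pair("NOX", "O3")))
})

test_that("sum_fields superposes member surfaces", {
  g <- model_grid(6, 7)
  p <- pp_pair("SO2", "PM25")
  set.seed(42)
  f <- random_field(g, p)
  zero <- sensitivity_field(g, matrix(0, 6, 7), "Z", "JAN", p)
  expect_equal(sum_fields(list(f, zero))$values, f$values)
  neg <- sensitivity_field(g, -f$values, "N", "JAN", p)
  expect_equal(sum_fields(list(f, neg))$values, matrix(0, 6, 7))

  plumes <- lapply(1:3, function(k) random_field(g, p, run_id = k, seed = k))
  total <- sum_fields(plumes, run_id = "G")$values
  # brute-force cell-by-cell total
  expected <- matrix(0, 6, 7)
  for (i in 1:6) for (j in 1:7)
    for (k in 1:3) expected[i, j] <- expected[i, j] + plumes[[k]]$values[i, j]
  expect_equal(total, expected)
  expect_equal(sum_fields(plumes)$run_id, "1")

  f2 <- random_field(g, p, month = "JUL", seed = 9)
  expect_error(sum_fields(list(f, f2)), "months")
  f3 <- random_field(g, pp_pair("NOX", "PM25"), seed = 9)
  expect_error(sum_fields(list(f, f3)), "pairs")
  f4 <- random_field(model_grid(6, 7, 12), p, seed = 9)
  expect_error(sum_fields(list(f, f4)), "grids")
})

test_that("sum_fields is commutative and associative", {
  g <- model_grid(5, 5)
  p <- pp_pair("PEC", "PM25")
  fs <- lapply(1:4, function(k) random_field(g, p, seed = 100 + k))
  ref <- sum_fields(fs)$values
  for (rep in 1:5) {
    perm <- sample(4)
    expect_equal(sum_fields(fs[perm])$values, ref, tolerance = 1e-12)
  }
  left <- sum_fields(list(sum_fields(fs[1:2]), fs[[3]], fs[[4]]))$values
  expect_equal(left, ref, tolerance = 1e-12)
})

test_that("CSV round trip preserves values and metadata", {
  g <- model_grid(10, 12, 36)
  set.seed(7)
  f <- random_field(g, pp_pair("NOX", "O3"), month = "JUL", run_id = "RG7")
  path <- withr::local_tempfile(fileext = ".csv")
  write_field(f, path)
  f2 <- read_field(path)
  expect_equal(f2$values, f$values, tolerance = 1e-12)
  expect_identical(f2$run_id, "RG7")
  expect_identical(f2$month, "JUL")
  expect_identical(format(f2$pair), "NOX_O3")
  expect_equal(f2$grid$cell_size_km, 36)
})

test_that("malformed CSV metadata is rejected by attribute name", {
  g <- model_grid(2, 2)
  f <- random_field(g, pp_pair("SO2", "PM25"), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field(f, path)
  lines <- readLines(path)
  lines[1] <- sub("precursor=SO2,", "", lines[1])
  writeLines(lines, path)
  expect_error(read_field(path), "precursor")
  writeLines(lines[-1], path)
  expect_error(read_field(path), "metadata")
})

test_that("NetCDF and CSV writes of the same field re-read equal", {
  skip_if_not_installed("ncdf4")
  g <- model_grid(10, 12)
  set.seed(11)
  f <- random_field(g, pp_pair("POC", "PM25"), run_id = "X1")
  nc <- withr::local_tempfile(fileext = ".nc")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_field(f, nc)
  write_field(f, cs)
  fn <- read_field(nc)
  fc <- read_field(cs)
  expect_equal(fn$values, f$values, tolerance = 1e-12)
  expect_equal(fn$values, fc$values, tolerance = 1e-12)
  expect_identical(fn$run_id, fc$run_id)
  expect_identical(fn$month, fc$month)
  expect_identical(format(fn$pair), format(fc$pair))
})

test_that("run groups enforce size and sector consistency", {
  fp <- data.frame(i = 1, j = 1, weight = 1)
  em <- list(JAN = c(SO2 = 10), JUL = c(SO2 = 10))
  a <- source_definition("A", "EGU", em, fp)
  b <- source_definition("B", "EGU", em, fp)
  rc <- source_definition("C", "RC", em, fp)
  expect_s3_class(run_group("G", "EGU", list(a, b)), "run_group")
  expect_error(run_group("G", "EGU", list()), "1 to 3")
  expect_error(run_group("G", "EGU", list(a, b, rc, a)), "1 to 3")
  expect_error(run_group("G", "EGU", list(a, rc)), "share the sector")
  expect_error(source_definition("A", "EGU", em,
                                 data.frame(i = 1, j = 1, weight = 0.5)),
               "sum to 1")
  expect_error(source_definition("A", "EGU",
                                 list(JAN = c(SO2 = -1), JUL = c(SO2 = 1)),
                                 fp), "nonnegative")
})
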