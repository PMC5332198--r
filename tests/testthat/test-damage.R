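test_that("monthly damage functions follow the deaths-per-kton arithmetic", {
  # 84 deaths/yr over 100 tons/month (1,200 tons/yr): 70 per 1,000 tons,
  # i.e. 0.07 deaths per ton
  h <- monthly_hdf(84, 100)
  expect_equal(h$deaths_per_kton, 70)
  expect_equal(h$annual_emissions_tons, 1200)
  expect_false(h$low_emission_flag)
  expect_equal(h$deaths_per_kton / 1000, 0.07)

  expect_equal(monthly_hdf(0, 100)$deaths_per_kton, 0)

  # miniscule-emissions pathology: 0.05 deaths/yr over 0.02 tons/yr
  h2 <- monthly_hdf(0.05, 0.02 / 12)
  expect_equal(h2$deaths_per_kton, 2500)

  h3 <- monthly_hdf(10, 0)
  expect_true(is.na(h3$deaths_per_kton))
  expect_true(h3$low_emission_flag)
  expect_error(monthly_hdf(10, -1), "nonnegative")
})

test_that("annual damage functions are signed means of the monthly pair", {
  p <- pp_pair("SO2", "PM25")
  mk <- function(deaths, tons, period)
    monthly_hdf(deaths, tons, "OH", "EGU", p, period)
  expect_equal(annual_hdf(mk(70 * 1.2, 100, "JAN"),
                          mk(70 * 1.2, 100, "JUL"))$deaths_per_kton, 70)
  expect_equal(annual_hdf(mk(120 * 1.2, 100, "JAN"),
                          mk(20 * 1.2, 100, "JUL"))$deaths_per_kton, 70)
  # signed ozone damage functions average through zero
  po3 <- pp_pair("NOX", "O3")
  jan <- monthly_hdf(-4 * 1.2, 100, "OH", "EGU", po3, "JAN")
  jul <- monthly_hdf(10 * 1.2, 100, "OH", "EGU", po3, "JUL")
  ann <- annual_hdf(jan, jul)
  expect_equal(ann$deaths_per_kton, 3)
  expect_equal(ann$period, "ANNUAL")
  other <- monthly_hdf(1, 1, "PA", "EGU", po3, "JUL")
  expect_error(annual_hdf(jan, other), "share")
  flagged <- monthly_hdf(5, 0, "OH", "EGU", po3, "JUL")
  expect_true(annual_hdf(jan, flagged)$low_emission_flag)
})

hdf_table <- function(states, tons, sector = "EGU", prec = "PEC",
                      poll = "PM25") {
  do.call(rbind, Map(function(s, t)
    monthly_hdf(1, t / 12, s, sector, pp_pair(prec, poll), "JAN"),
    states, tons))
}

test_that("low-emission flagging combines rank and absolute-floor rules", {
  # six states, one with 0.02 tons/yr: the floor rule flags it
  tab <- hdf_table(paste0("S", 1:6), c(0.02, 120, 340, 90, 800, 55))
  out <- flag_low_emission(tab, n_lowest = 0, floor_tons = 1)
  expect_identical(out$low_emission_flag, tab$source_state == "S1")

  # equal emissions: rank rule flags exactly five, ties broken by state id
  tab2 <- hdf_table(paste0("S", 1:8), rep(100, 8))
  out2 <- flag_low_emission(tab2, n_lowest = 5, floor_tons = 1)
  expect_equal(sum(out2$low_emission_flag), 5L)
  expect_identical(out2$source_state[out2$low_emission_flag],
                   paste0("S", 1:5))

  # small tables clamp the rank rule at the table size
  tab3 <- hdf_table(paste0("S", 1:4), c(10, 20, 30, 40))
  out3 <- flag_low_emission(tab3, n_lowest = 5)
  expect_true(all(out3$low_emission_flag))

  expect_error(flag_low_emission(tab3[0, ]), "non-empty")
})

test_that("lowering the absolute floor never adds flags", {
  set.seed(31)
  tab <- hdf_table(paste0("S", 1:12), exp(runif(12, -4, 8)))
  floors <- c(100, 10, 1, 0.01)
  prev <- NULL
  for (fl in floors) {
    out <- flag_low_emission(tab, n_lowest = 2, floor_tons = fl)
    if (!is.null(prev))
      expect_true(all(out$low_emission_flag <= prev))
    prev <- out$low_emission_flag
  }
})

test_that("summary percentiles match an independent interpolation oracle", {
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  # single unflagged state: every percentile equals its value
  tab1 <- hdf_table("S1", 500)
  imp1 <- data.frame(source_state = "S1", sector = "EGU",
                     precursor = "PEC", pollutant = "PM25",
                     period = "ANNUAL", delta_deaths = 3)
  s1 <- summarize_burden(imp1, tab1)
  expect_true(all(unlist(s1$hdf_percentiles[c("p5", "q1", "median",
                                              "q3", "p95")]) ==
                    tab1$deaths_per_kton[1]))

  # nine states with values 1..9: median 5
  tab9 <- hdf_table(paste0("S", 1:9), rep(1200, 9))
  tab9$deaths_per_kton <- 1:9
  imp9 <- data.frame(source_state = paste0("S", 1:9), sector = "EGU",
                     precursor = "PEC", pollutant = "PM25",
                     period = "ANNUAL", delta_deaths = 1:9)
  s9 <- summarize_burden(imp9, tab9)
  expect_equal(s9$hdf_percentiles$median, 5)

  # random values against the sort-and-interpolate oracle
  set.seed(77)
  vals <- rnorm(17, 40, 15)
  tabr <- hdf_table(sprintf("S%02d", 1:17), rep(1200, 17))
  tabr$deaths_per_kton <- vals
  impr <- data.frame(source_state = tabr$source_state, sector = "EGU",
                     precursor = "PEC", pollutant = "PM25",
                     period = "ANNUAL", delta_deaths = vals)
  sr <- summarize_burden(impr, tabr)
  for (k in seq_along(probs))
    expect_equal(unlist(sr$hdf_percentiles[1, c("p5", "q1", "median", "q3",
                                                "p95")])[[k]],
                 percentile_oracle(vals, probs[k]), tolerance = 1e-12)
  expect_true(all(diff(unlist(sr$hdf_percentiles[1, c("p5", "q1", "median",
                                                      "q3", "p95")])) >= 0))
})

test_that("sector death ratios handle zero denominators as missing", {
  imp <- rbind(
    data.frame(source_state = "S1", sector = "RC", precursor = "POC",
               pollutant = "PM25", period = "ANNUAL", delta_deaths = 10),
    data.frame(source_state = "S1", sector = "EGU", precursor = "SO2",
               pollutant = "PM25", period = "ANNUAL", delta_deaths = 40),
    data.frame(source_state = "S2", sector = "RC", precursor = "POC",
               pollutant = "PM25", period = "ANNUAL", delta_deaths = 0),
    data.frame(source_state = "S2", sector = "EGU", precursor = "SO2",
               pollutant = "PM25", period = "ANNUAL", delta_deaths = 5))
  tab <- hdf_table(c("S1", "S2"), c(100, 100))
  s <- summarize_burden(imp, tab)
  expect_equal(s$sector_ratios$egu_rc_ratio[s$sector_ratios$source_state ==
                                              "S1"], 4)
  expect_true(is.na(s$sector_ratios$egu_rc_ratio[
    s$sector_ratios$source_state == "S2"]))
})

test_that("flagged states are excluded from percentiles but retained", {
  tab <- hdf_table(paste0("S", 1:6), c(0.5, 1200, 1200, 1200, 1200, 1200))
  tab$deaths_per_kton <- c(9999, 10, 20, 30, 40, 50)
  tab <- flag_low_emission(tab, n_lowest = 0, floor_tons = 1)
  imp <- data.frame(source_state = tab$source_state, sector = "EGU",
                    precursor = "PEC", pollutant = "PM25",
                    period = "ANNUAL", delta_deaths = 1)
  s <- summarize_burden(imp, tab)
  expect_equal(s$hdf_percentiles$n_states, 5L)
  expect_equal(s$hdf_percentiles$median, 30)
  expect_equal(nrow(tab), 6L)  # flagged row retained in the table itself
})
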