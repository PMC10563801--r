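test_that("Pettitt statistic matches its definition on a designed step", {
  s <- data.frame(year = 2001:2010, value = c(rep(0, 5), rep(10, 5)))
  pt <- pettitt(s)
  expect_equal(pt$K, 25)
  expect_equal(pt$change_index, 5L)
  expect_equal(pt$p_value, 2 * exp(-3750 / 1100), tolerance = 1e-12)
  # constant series: degenerate, not an error
  pc <- pettitt(data.frame(year = 1:12, value = rep(3, 12)))
  expect_true(pc$degenerate)
  expect_equal(pc$K, 0)
  expect_equal(pc$p_value, 1)
  expect_true(is.na(pc$change_year))
})

test_that("rank-based Pettitt equals the brute-force double loop", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(10:50, 1)
    x <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE)  # heavy ties
         else rnorm(n)
    pt <- pettitt(data.frame(year = seq_len(n), value = x))
    bf <- bf_pettitt(x)
    expect_identical(unname(pt$U), bf$U)
    expect_equal(pt$K, bf$K)
    if (bf$K > 0) expect_equal(pt$change_index, bf$change_index)
  }
})

test_that("the approximate p-value is near-nominal under an iid null", {
  set.seed(33)
  rej <- mean(replicate(2000, {
    pettitt(data.frame(year = 1:45, value = rnorm(45)))$p_value < 0.05
  }))
  expect_lte(rej, 0.08)
})

test_that("split regression recovers noiseless piecewise structure", {
  yrs <- 1850:2010
  step <- data.frame(year = yrs, value = 2 + 5 * (yrs >= 1946))
  d <- suppressWarnings(split_regression(step, 1946))
  expect_equal(d$step_offset, 5, tolerance = 1e-9)
  expect_equal(d$slope_before, 0, tolerance = 1e-12)
  expect_equal(d$slope_after, 0, tolerance = 1e-12)
  hinge <- data.frame(year = yrs,
                      value = 0.1 * pmax(yrs - 1950, 0))
  d2 <- suppressWarnings(split_regression(hinge, 1950))
  expect_equal(d2$slope_after, 0.1, tolerance = 1e-12)
  expect_equal(d2$step_offset, 0, tolerance = 1e-9)
  # a side with too few points leaves that slope undefined
  d3 <- suppressWarnings(split_regression(step[step$year >= 1944, ], 1946))
  expect_true(is.na(d3$slope_before))
  expect_true(is.na(d3$step_offset))
})

test_that("decomposition contributions add up to the fitted change", {
  site <- list(x = 0)
  cfg <- scenario_config(noise_sd = 0)
  s <- gen_core_timeseries(site, cfg, seed = 1)
  dec <- suppressWarnings(decompose_series(s))
  expect_true(dec$significant)
  total_fitted <- dec$fitted_at(2010) - dec$fitted_at(1850)
  slope_before_part <- dec$slope_before * (dec$change_year - 1850)
  expect_equal(dec$step_component + dec$trend_component +
                 slope_before_part, total_fitted, tolerance = 1e-8)
  expect_true(dec$step_attributed_to_inlet)
})

test_that("step detection attributes correctly at the stated noise level", {
  site <- list(x = 0)
  cfg <- scenario_config()  # step 3 at 1946, slope 0.05, noise 0.3, AR 0.3
  hits <- 0; offs <- numeric(0)
  for (sd in 1:50) {
    s <- gen_core_timeseries(site, cfg, seed = 400 + sd, n_points = 45)
    dec <- suppressWarnings(decompose_series(s))
    if (isTRUE(dec$step_attributed_to_inlet)) hits <- hits + 1
    if (!is.na(dec$step_offset)) offs <- c(offs, dec$step_offset)
  }
  expect_gte(hits / 50, 0.85)
  # a pure trend with no step is not attributed to the inlet when the
  # detected change falls outside the construction window
  cfg2 <- scenario_config(step_magnitude = 0, trend_start = 1860,
                          trend_end = 2000, trend_slope = 0.05,
                          noise_sd = 0.2)
  out_of_window <- 0
  for (sd in 1:30) {
    s <- gen_core_timeseries(site, cfg2, seed = 700 + sd, n_points = 45)
    dec <- suppressWarnings(decompose_series(s))
    cy <- dec$change_year
    if (is.na(cy) || cy < 1936 || cy > 1956) {
      expect_false(isTRUE(dec$step_attributed_to_inlet) &&
                     (cy < 1936 || cy > 1956))
      out_of_window <- out_of_window + 1
    }
  }
  expect_gte(out_of_window / 30, 0.8)
})

test_that("DIF/ABS summaries behave like differences and endpoints", {
  s <- data.frame(year = c(1850, seq(1860, 2000, 10), 2010),
                  value = c(5.2, rnorm(15), 14.8))
  da <- dif_abs(s)
  expect_equal(da$DIF, 9.6)
  expect_equal(da$ABS, 14.8)
  expect_true(da$exact)
  # shift equivariance
  s2 <- s; s2$value <- s2$value + 3
  da2 <- dif_abs(s2)
  expect_equal(da2$DIF, da$DIF)
  expect_equal(da2$ABS, da$ABS + 3)
  # constant series
  expect_equal(dif_abs(data.frame(year = c(1850, 2010),
                                  value = c(2, 2)))$DIF, 0)
  # nearest-year substitution within tolerance, error beyond it
  s3 <- data.frame(year = c(1853, 2008), value = c(1, 4))
  expect_false(dif_abs(s3)$exact)
  expect_error(dif_abs(data.frame(year = c(1900, 2010),
                                  value = c(1, 2))), "within 5 years")
})

test_that("fraction-before reflects the fitted change trajectory", {
  # pure linear trend across the record
  lin <- list(fitted_at = function(y) 0.01 * (y - 1850),
              years = c(1850, 2010))
  expect_equal(fraction_before(lin, 1988), (1988 - 1850) / 160)
  # pure step at 1946: all change precedes monitoring
  stp <- list(fitted_at = function(y) 5 * (y >= 1946),
              years = c(1850, 2010))
  expect_equal(fraction_before(stp, 1988), 1)
  # generator closed form: step 3 at 1946 + slope 0.05 over 1950-1980
  gen <- list(fitted_at = function(y) {
    3 * (y >= 1946) + 0.05 * pmin(pmax(y - 1950, 0), 30)
  }, years = c(1850, 2010))
  expect_equal(fraction_before(gen, 1988), 1)
  expect_equal(fraction_before(gen, 1960), 3.5 / 4.5, tolerance = 1e-12)
  # zero total change is flagged undefined
  flat <- list(fitted_at = function(y) 1, years = c(1850, 2010))
  expect_warning(fr <- fraction_before(flat, 1988), "undefined")
  expect_true(is.na(fr))
})

test_that("water-quality pairing reports the expected correlations", {
  yrs <- 1990:2010
  sed <- data.frame(year = yrs, value = seq(5, 10, length.out = 21))
  mk_rec <- function(no3_by_year) {
    do.call(rbind, lapply(seq_along(yrs), function(i) {
      data.frame(station_id = "W", date = sprintf("%d-06-15", yrs[i]),
                 no3 = no3_by_year[i], salinity = 30)
    }))
  }
  # nitrate equal to the sediment series gives r = 1
  pw <- pair_with_water_quality(sed, mk_rec(sed$value), "W")
  expect_equal(pw$r_no3, 1)
  expect_equal(pw$n, 21)
  # constant nitrate is flagged, correlation undefined
  pc <- pair_with_water_quality(sed, mk_rec(rep(8, 21)), "W")
  expect_true(pc$constant_no3)
  expect_true(is.na(pc$r_no3))
  # independent pairs show no systematic correlation
  set.seed(55)
  rs <- replicate(200, {
    pair_with_water_quality(
      data.frame(year = yrs, value = rnorm(21)),
      mk_rec(rnorm(21)), "W")$r_no3
  })
  expect_lt(mean(abs(rs)), 0.25)
})
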