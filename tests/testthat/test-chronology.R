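noiseless_cfg <- function(acc = 0.25) {
  scenario_config(accretion_rate = acc, profile_noise_cv = 0)
}

test_that("marker detection recovers the generator's event depths", {
  cfg <- noiseless_cfg()
  pr <- gen_radionuclide_profile(cfg, seed = 1, core_depth = 40,
                                 slab_thickness = 1)
  mk <- detect_markers(pr, cfg$collection_year)
  truth <- attr(pr, "truth")
  expect_setequal(mk$kind, c("surface", "cs_basal_1953", "cs_peak_1963",
                             "pb_peak_1974"))
  get <- function(k) mk$depth_cm[mk$kind == k]
  expect_lt(abs(get("cs_basal_1953") - truth$depth_1953), 1.5)
  expect_lt(abs(get("cs_peak_1963") - truth$depth_1963), 1)
  expect_lt(abs(get("pb_peak_1974") - truth$depth_1974), 1)
})

test_that("marker detection never fabricates and breaks ties shallow", {
  prof <- data.frame(top_cm = c(0, 2, 4, 6), bottom_cm = c(2, 4, 6, 8),
                     cs137 = 0, total_pb = c(10, 30, 30, 10))
  mk <- detect_markers(prof, 2010)
  expect_setequal(mk$kind, c("surface", "pb_peak_1974"))
  expect_equal(mk$depth_cm[mk$kind == "pb_peak_1974"], 3)  # shallower tie
  prof$cs137 <- c(1, 5, 5, 0.01)
  mk2 <- detect_markers(prof, 2010, cs_threshold = 0.1)
  expect_equal(mk2$depth_cm[mk2$kind == "cs_peak_1963"], 3)
  expect_equal(mk2$depth_cm[mk2$kind == "cs_basal_1953"], 6)
})

test_that("CRS dating inverts the constant-accretion generator", {
  cfg <- noiseless_cfg(0.25)
  # 4 half-lives of 210Pb span about 89 years ~ 22 cm at this accretion
  pr <- gen_radionuclide_profile(cfg, seed = 1, core_depth = 50,
                                 slab_thickness = 1)
  cr <- crs_ages(pr, cfg$supported_pb210)
  truth <- attr(pr, "truth")
  in_range <- cr$depth_cm > 0 & cr$depth_cm <= 4 * 22.3 * 0.25
  rel_err <- abs(cr$age_yr[in_range] - truth$age_at(cr$depth_cm[in_range])) /
    truth$age_at(cr$depth_cm[in_range])
  expect_lt(max(rel_err), 0.02)
  expect_equal(cr$age_yr[cr$depth_cm == 0], 0)
})

test_that("CRS dates a constructed half-inventory depth at one half-life", {
  # two thick slabs holding equal inventory: the boundary between them
  # sits at exactly one half-life
  cfg <- noiseless_cfg(0.5)
  pr <- gen_radionuclide_profile(cfg, seed = 1, core_depth = 120,
                                 slab_thickness = 0.5)
  cr <- crs_ages(pr, cfg$supported_pb210)
  z_half <- 0.5 * 22.3
  age_at_half <- approx(cr$depth_cm, cr$age_yr, z_half)$y
  expect_equal(age_at_half, 22.3, tolerance = 0.01)
})

test_that("two tight markers pin the posterior accretion slope", {
  mk <- data.frame(depth_cm = c(0, 25), calendar_year = c(2010, 1963),
                   sd_years = c(0.01, 1), kind = c("surface", "cs"))
  post <- fit_age_depth(NULL, mk, collection_year = 2010,
                        priors = list(acc_mean = 2, acc_shape = 4),
                        seed = 5)
  expect_equal(mean(post$accretion_draws), 25 / 47, tolerance = 0.1)
})

test_that("posterior draws are monotone and the mean sits in its envelope", {
  cfg <- noiseless_cfg(0.25)
  pr <- gen_radionuclide_profile(cfg, seed = 2, core_depth = 50)
  mk <- detect_markers(pr, cfg$collection_year)
  post <- fit_age_depth(pr, mk, collection_year = cfg$collection_year,
                        seed = 7)
  # every draw is a non-increasing year (non-decreasing age) with depth
  expect_true(all(apply(post$year_draws, 1,
                        function(y) all(diff(y) <= 1e-9))))
  expect_true(all(post$summary$mean_year >= post$summary$lo95 - 1e-9))
  expect_true(all(post$summary$mean_year <= post$summary$hi95 + 1e-9))
  # parameter recovery on this core
  expect_equal(mean(post$accretion_draws), 0.25, tolerance = 0.15)
  expect_equal(mean(post$influx_draws), cfg$pb210_influx,
               tolerance = 0.25)
})

test_that("Bayesian and CRS ages agree on noiseless constant accretion", {
  cfg <- noiseless_cfg(0.25)
  pr <- gen_radionuclide_profile(cfg, seed = 3, core_depth = 40,
                                 slab_thickness = 2)
  mk <- detect_markers(pr, cfg$collection_year)
  post <- fit_age_depth(pr, mk, collection_year = cfg$collection_year,
                        seed = 13)
  cr <- crs_ages(pr, cfg$supported_pb210)
  bayes_age <- cfg$collection_year -
    approx(post$depth_cm, post$summary$mean_year, cr$depth_cm)$y
  dated <- cr$defined & cr$depth_cm <= 22.3 * 0.25 * 4
  expect_lt(max(abs(bayes_age[dated] - cr$age_yr[dated])), 5)
})

test_that("composite of one core is that core; pooling widens intervals", {
  cfg <- noiseless_cfg(0.25)
  pr <- gen_radionuclide_profile(cfg, seed = 4, core_depth = 50)
  mk <- detect_markers(pr, cfg$collection_year)
  post <- fit_age_depth(pr, mk, collection_year = cfg$collection_year,
                        seed = 17)
  comp1 <- composite_chronology(list(post), depth_grid = post$depth_cm)
  expect_equal(comp1$mean_year, post$summary$mean_year, tolerance = 1e-12)
  expect_equal(comp1$lo95, post$summary$lo95, tolerance = 1e-12)
  # N identical posteriors compose to the same curve
  comp3 <- composite_chronology(list(post, post, post),
                                depth_grid = post$depth_cm)
  expect_equal(comp3$mean_year, post$summary$mean_year, tolerance = 1e-12)
  # two disagreeing cores: pooled CI at least as wide as either core's
  cfg2 <- noiseless_cfg(0.45)
  pr2 <- gen_radionuclide_profile(cfg2, seed = 5, core_depth = 50)
  post2 <- fit_age_depth(pr2, detect_markers(pr2, 2010),
                         collection_year = 2010, seed = 19)
  grid <- seq(0, 50, by = 5)
  compd <- composite_chronology(list(post, post2), depth_grid = grid)
  w_pool <- compd$hi95 - compd$lo95
  w1 <- approx(post$depth_cm, post$summary$hi95 - post$summary$lo95,
               grid)$y
  deep <- grid >= 20  # cores disagree strongly at depth
  expect_true(all(w_pool[deep] >= w1[deep] - 1e-9))
  # pooled mean is monotone even where the cores disagree
  expect_true(all(diff(compd$mean_year) <= 1e-9))
})

test_that("interval dating assigns eras and is stable to grid refinement", {
  chron <- data.frame(depth_cm = seq(0, 60, 1),
                      mean_year = 2010 - seq(0, 60, 1) / 0.25,
                      lo95 = 2010 - seq(0, 60, 1) / 0.25 - 4,
                      hi95 = 2010 - seq(0, 60, 1) / 0.25 + 4)
  iv <- data.frame(top_cm = c(0, 10, 100), bottom_cm = c(10, 20, 110))
  dated <- apply_chronology(chron, iv)
  expect_equal(dated$mean_year[1], 2010 - 5 / 0.25)  # 1990
  expect_equal(dated$era[1], "1981-2010")
  expect_false(dated$in_range[3])
  expect_true(is.na(dated$era[3]))
  # era of a 1975 midpoint
  iv2 <- data.frame(top_cm = 0.25 * 35 - 1, bottom_cm = 0.25 * 35 + 1)
  expect_equal(apply_chronology(chron, iv2)$era, "1963-1981")
  # halving the grid moves interval mean years by < 0.5 yr
  chron2 <- chron[seq(1, 61, 2), ]
  d1 <- apply_chronology(chron, iv[1:2, ])
  d2 <- apply_chronology(chron2, iv[1:2, ])
  expect_lt(max(abs(d1$mean_year - d2$mean_year)), 0.5)
})
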