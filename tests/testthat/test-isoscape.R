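test_that("empirical semivariogram matches the Matheron formula", {
  ev <- empirical_variogram(data.frame(x = c(0, 10), y = c(0, 0)),
                            c(0, 2), n_bins = 1, max_lag = 15)
  expect_equal(ev$gamma, 2)       # (2^2) / (2 * 1)
  expect_equal(ev$n_pairs, 1L)
  set.seed(2)
  pts <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100))
  evc <- empirical_variogram(pts, rep(3.7, 30))
  expect_true(all(evc$gamma == 0))
  expect_error(empirical_variogram(data.frame(x = c(1, 1), y = c(2, 2)),
                                   c(0, 1)), "coincident")
})

test_that("WLS fitting recovers a noiseless spherical curve", {
  h <- seq(5, 150, length.out = 15)
  true <- make_model("spherical", nugget = 0.1, psill = 1.2, range = 80)
  emp <- structure(data.frame(lag = h, gamma = vgm_eval(true, h),
                              n_pairs = 40L),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$psill, 1.2, tolerance = 0.05)
  expect_equal(fit$range, 80, tolerance = 0.05)
  expect_equal(vgm_eval(fit, 0), fit$nugget)
  # all-zero semivariances collapse to a degenerate zero model
  emp0 <- structure(data.frame(lag = h, gamma = 0, n_pairs = 40L),
                    class = c("empirical_variogram", "data.frame"))
  fit0 <- fit_variogram(emp0, "gaussian")
  expect_equal(fit0$nugget, 0)
  expect_equal(fit0$psill, 0)
})

test_that("kriging is an exact unbiased interpolator", {
  set.seed(3)
  pts <- data.frame(x = runif(9, 0, 100), y = runif(9, 0, 100))
  v <- 1 + 0.02 * pts$x + rnorm(9, sd = 0.4)
  mod <- make_model("spherical", nugget = 0, psill = 1, range = 60)
  kr <- krige(pts, v, mod, pts)
  expect_equal(kr$pred, v, tolerance = 1e-8)
  expect_equal(kr$var, rep(0, 9), tolerance = 1e-8)
  expect_equal(unname(rowSums(kr$weights)), rep(1, 9), tolerance = 1e-10)
  # constant data predict the constant everywhere, any family
  for (fam in c("spherical", "exponential", "gaussian", "circular")) {
    m <- make_model(fam, nugget = 0.2, psill = 0.7, range = 40)
    kc <- krige(pts, rep(5.5, 9), m,
                data.frame(x = c(10, 90), y = c(80, 15)))
    expect_equal(kc$pred, c(5.5, 5.5))
  }
  # duplicate coordinates are averaged, then solved
  pts_d <- rbind(pts, pts[1, ])
  v_d <- c(v, v[1] + 2)
  kd <- krige(pts_d, v_d, mod, pts[1, , drop = FALSE])
  expect_equal(kd$pred, v[1] + 1, tolerance = 1e-8)
})

test_that("universal kriging with linear drift reproduces a plane", {
  set.seed(4)
  pts <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100))
  plane <- 2 + 0.05 * pts$x - 0.03 * pts$y
  mod <- make_model("linear_drift1", nugget = 0, psill = 0.5, range = 50,
                    drift_order = 1L)
  tg <- data.frame(x = c(25, 75), y = c(60, 30))
  kr <- krige(pts, plane, mod, tg)
  expect_equal(kr$pred, 2 + 0.05 * tg$x - 0.03 * tg$y, tolerance = 1e-8)
})

test_that("kriging agrees with a hand-assembled dense solve", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    pts <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
    v <- rnorm(n)
    fam <- sample(c("spherical", "exponential", "gaussian"), 1)
    dord <- sample(0:1, 1)
    if (dord == 1 && n < 5) dord <- 0
    mod <- make_model(fam, nugget = runif(1, 0, 0.3),
                      psill = runif(1, 0.5, 2),
                      range = runif(1, 30, 120),
                      drift_order = as.integer(dord))
    tg <- data.frame(x = runif(1, 0, 100), y = runif(1, 0, 100))
    kr <- krige(pts, v, mod, tg)
    bf <- bf_krige_one(as.matrix(pts), v, mod, tg)
    expect_lt(abs(kr$pred - bf$pred), 1e-8)
    expect_lt(abs(kr$var - bf$var), 1e-8)
    if (dord == 0) {
      expect_lt(abs(sum(kr$weights) - 1), 1e-10)
    }
    # when all weights are non-negative the prediction is data-bounded
    if (all(kr$weights >= 0)) {
      expect_gte(kr$pred, min(v) - 1e-9)
      expect_lte(kr$pred, max(v) + 1e-9)
    }
  }
})

test_that("holdout selection is deterministic and ties go spherical", {
  set.seed(6)
  pts <- data.frame(x = runif(30, 0, 1000), y = runif(30, 0, 300))
  v <- rnorm(30)
  s1 <- select_variogram(pts, v, seed = 42)
  s2 <- select_variogram(pts, v, seed = 42)
  expect_identical(s1$holdout, s2$holdout)
  expect_identical(s1$rmse, s2$rmse)
  expect_equal(length(s1$holdout), max(2, round(0.15 * 30)))
  # constant field: every family predicts perfectly; spherical wins tie
  sc <- select_variogram(pts, rep(2, 30), seed = 7)
  expect_true(all(sc$rmse$rmse[!sc$rmse$failed] < 1e-8))
  expect_equal(sc$best, "spherical")
})

test_that("era isoscapes honour site data and the configured ordering", {
  cfg <- scenario_config(n_sites = 24, channel_length = 3000,
                         channel_width = 400)
  for (er in names(cfg$field_params)) {
    cfg$field_params[[er]]$sill <- 0
    cfg$field_params[[er]]$nugget <- 0
  }
  sites <- gen_sites(cfg)
  eras <- era_bins()
  samples <- do.call(rbind, lapply(eras$label, function(er) {
    f <- gen_true_field(cfg, er, seed = 1, points = sites[, c("x", "y")])
    data.frame(site_id = sites$site_id, era = er, d15N = f$value)
  }))
  maps <- build_isoscapes(samples, sites, "d15N", eras,
                          cell_size = 200, force_family = "spherical")
  expect_equal(length(maps), 6)
  # nugget-free kriging reproduces the at-site values exactly
  m1 <- maps[["1726-1839"]]
  at_site <- krige(m1$site_values, m1$site_values$value, m1$model,
                   m1$site_values[, c("x", "y")])
  expect_equal(at_site$pred, m1$site_values$value, tolerance = 1e-6)
  # per-era map means are ordered as the configured mouth endmembers
  means <- sapply(maps, isoscape_mean)
  expect_true(all(diff(means) > 0))
  # an era with too few sites is skipped with a warning
  few <- samples[samples$era == "1726-1839", ][1:3, ]
  expect_warning(
    got <- build_isoscapes(few, sites, "d15N", eras, cell_size = 200,
                           force_family = "spherical"),
    "< 4 sites")
  expect_equal(length(got), 0)
})

test_that("isoscapes write valid ESRI ASCII grids with sidecars", {
  cfg <- scenario_config(n_sites = 12, channel_length = 1500,
                         channel_width = 300)
  sites <- gen_sites(cfg)
  f <- gen_true_field(cfg, "1981-2010", seed = 2,
                      points = sites[, c("x", "y")])
  samples <- data.frame(site_id = sites$site_id, era = "1981-2010",
                        d15N = f$value)
  maps <- build_isoscapes(samples, sites, "d15N", cell_size = 150,
                          force_family = "spherical")
  path <- tempfile(fileext = ".asc")
  write_isoscape_asc(maps[[1]], path)
  hdr <- readLines(path, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_match(hdr[6], "NODATA_value")
  body <- utils::read.table(path, skip = 6)
  expect_equal(nrow(body), length(maps[[1]]$ys))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$family, "spherical")
  expect_equal(side$variable, "d15N")
})
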