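# End-to-end orchestration: materialise a synthetic estuary on disk and
# run chronology -> era binning -> isoscapes -> change-point
# decomposition -> nitrogen budget, emitting a reproducible JSON + CSV
# report. The exported functions are the pipeline interface; a thin
# Rscript wrapper for shell use lives in scripts/pipeline.R.

#' Mini-estuary scenario used by the test fixtures
#'
#' A 12-site, 3-focal-core estuary on a 2 km channel with accretion
#' chosen so that 10/25-cm sampling intervals date into all six mapping
#' eras, and low-noise radionuclide profiles.
#'
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
mini_scenario <- function(...) {
  args <- utils::modifyList(
    list(n_sites = 12, n_focal = 3, channel_length = 2000,
         channel_width = 200, accretion_rate = 0.45,
         profile_noise_cv = 0.02),
    list(...))
  do.call(scenario_config, args)
}

# Deterministic sub-seeds for the pipeline stages.
.sub_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(2^30, n))
}

.depth_intervals <- function(core_depth = 125) {
  top <- c(seq(0, 40, by = 10), seq(50, core_depth - 25, by = 25))
  data.frame(top_cm = top,
             bottom_cm = c(seq(10, 50, by = 10),
                           seq(75, core_depth, by = 25)))
}

#' Write a complete synthetic estuary fixture to disk
#'
#' Writes sites, a core-sample table (all sites, 10-cm intervals for
#' 0-50 cm and 25-cm intervals below), radionuclide profiles and
#' radiocarbon markers for the focal cores, annual isotope series for
#' the focal sites, monthly water-quality records at stations co-located
#' with the focal cores, the decadal watershed history, and a
#' ground-truth JSON with every injected parameter.
#'
#' @param config a [scenario_config()] (default [mini_scenario()]).
#' @param outdir output directory (created if needed).
#' @param seed global seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param core_depth core length, cm.
#' @return invisible list of the written file paths.
#' @export
run_simulate <- function(config = mini_scenario(), outdir, seed = 1,
                         core_depth = 125) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sites <- gen_sites(config)
  seeds <- .sub_seeds(seed, 4 + 3 * nrow(sites))
  eras <- era_bins()
  # one jointly-realized true field per era at the site locations
  fields <- lapply(seq_len(nrow(eras)), function(i) {
    gen_true_field(config, eras$label[i], seed = seeds[1] + i,
                   points = sites[, c("x", "y")])
  })
  names(fields) <- eras$label
  ivals <- .depth_intervals(core_depth)
  mids <- (ivals$top_cm + ivals$bottom_cm) / 2
  true_year <- config$collection_year - mids / config$accretion_rate
  true_era <- assign_era(true_year, eras)
  frac <- sites$x / config$channel_length
  rows <- list()
  meas_seed <- seeds[2]
  for (si in seq_len(nrow(sites))) {
    noise <- .with_seed(meas_seed + si,
                        matrix(stats::rnorm(length(mids) * 3),
                               ncol = 3))
    d15N <- vapply(seq_along(mids), function(k) {
      if (is.na(true_era[k])) return(NA_real_)
      fields[[true_era[k]]]$value[si]
    }, 0) + 0.2 * noise[, 1]
    d13C <- -24.6 - 0.8 * frac[si] + 0.5 * noise[, 2]
    cn_true <- 11 + 2 * frac[si] + 0.4 * noise[, 3]
    n_pct <- rep(0.25, length(mids))
    c_pct <- cn_true * n_pct * .ATOMIC_WEIGHT_C / .ATOMIC_WEIGHT_N
    rows[[si]] <- data.frame(
      site_id = sites$site_id[si], x = sites$x[si], y = sites$y[si],
      top_cm = ivals$top_cm, bottom_cm = ivals$bottom_cm,
      d15N = round(d15N, 6), d13C = round(d13C, 6),
      c_pct = round(c_pct, 6), n_pct = n_pct)
  }
  cores <- do.call(rbind, rows)
  focal <- sites[sites$role == "focal", , drop = FALSE]
  paths <- list(sites = file.path(outdir, "sites.csv"),
                cores = file.path(outdir, "cores.csv"),
                series = file.path(outdir, "series.csv"),
                markers = file.path(outdir, "markers_14c.csv"),
                watershed = file.path(outdir, "watershed.csv"),
                water_quality = file.path(outdir, "water_quality.csv"),
                truth = file.path(outdir, "truth.json"))
  utils::write.csv(sites, paths$sites, row.names = FALSE, quote = FALSE)
  write_core_table(cores, paths$cores)
  # focal profiles, series, deep radiocarbon anchors and water quality
  ser <- list(); mk <- list(); wq <- list()
  for (fi in seq_len(nrow(focal))) {
    sid <- focal$site_id[fi]
    prof <- gen_radionuclide_profile(config, seed = seeds[3] + fi,
                                     core_depth = 60)
    utils::write.csv(prof, file.path(outdir,
                                     paste0("profile_", sid, ".csv")),
                     row.names = FALSE, quote = FALSE)
    s <- gen_core_timeseries(focal[fi, ], config, seed = seeds[4] + fi)
    ser[[fi]] <- data.frame(site_id = sid, variable = "d15N",
                            year = s$year, value = round(s$value, 6))
    c14_depth <- c(80, 120)
    mk[[fi]] <- data.frame(
      site_id = sid, depth_cm = c14_depth,
      calendar_year = round(config$collection_year -
                              c14_depth / config$accretion_rate),
      sd_years = 15, kind = "radiocarbon")
    # monthly water quality tied to the site's annual series
    yrs <- 1990:2010
    ann <- s$value[match(yrs, s$year)]
    wq_noise <- .with_seed(seeds[3] + 500 + fi,
                           stats::rnorm(length(yrs) * 12, sd = 3))
    months <- rep(1:12, times = length(yrs))
    years_m <- rep(yrs, each = 12)
    base <- rep(pmax(30 * (ann - min(ann)) + 20, 1), each = 12)
    no3 <- pmax(base * (1 + 0.3 * sin(2 * pi * months / 12)) +
                  wq_noise, 0)
    wq[[fi]] <- data.frame(
      station_id = paste0("W_", sid),
      date = sprintf("%d-%02d-15", years_m, months),
      no3 = round(no3, 3),
      salinity = round(33 - 5 * focal$x[fi] / config$channel_length +
                         0.5 * sin(2 * pi * months / 12), 3))
  }
  utils::write.csv(do.call(rbind, ser), paths$series,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, mk), paths$markers,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, wq), paths$water_quality,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(gen_watershed_history(config), paths$watershed,
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    seed = seed, accretion_rate = config$accretion_rate,
    step_year = config$step_year,
    step_magnitude = config$step_magnitude,
    trend_start = config$trend_start, trend_end = config$trend_end,
    trend_slope = config$trend_slope,
    pb210_influx = config$pb210_influx,
    supported_pb210 = config$supported_pb210,
    focal_sites = focal$site_id,
    field_params = config$field_params)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Run the full pipeline on a simulated or observed dataset
#'
#' Stages: per-focal-core Bayesian chronology (event markers detected
#' from the radionuclide profile, plus any radiocarbon anchors), pooled
#' composite chronology, era assignment of every core sample, forced-
#' spherical isoscapes for d15N, d13C and molar C/N across the six eras,
#' Pettitt step/trend decomposition of each focal series (with DIF/ABS
#' and water-quality pairing when records are present), and the decadal
#' nitrogen budget. Writes a machine-readable report (JSON) plus CSV
#' tables, and a run log with stage timings; the report itself carries
#' no timestamps so that reruns under one seed are byte-identical.
#'
#' @param datadir directory produced by [run_simulate()] (or containing
#'   observed tables in the same layout).
#' @param outdir output directory.
#' @param seed global seed for the stochastic stages.
#' @param mcmc MCMC settings passed to [fit_age_depth()].
#' @param cell_size isoscape grid cell size, m.
#' @param nlm_params_path YAML parameter file for the nitrogen budget.
#' @return invisible report list (also written to `report.json`).
#' @export
run_all <- function(datadir, outdir, seed = 1,
                    mcmc = list(n_iter = 2000, seg_thick = 10),
                    cell_size = 100,
                    nlm_params_path = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
    message(msg)
  }
  tic <- function() proc.time()[["elapsed"]]
  stage_times <- list()

  sites <- utils::read.csv(file.path(datadir, "sites.csv"),
                           colClasses = c(site_id = "character"))
  cores <- read_core_table(file.path(datadir, "cores.csv"))
  seeds <- .sub_seeds(seed, 8)
  eras <- era_bins()

  # --- chronology ---------------------------------------------------
  t0 <- tic()
  focal_ids <- sites$site_id[sites$role == "focal"]
  c14_path <- file.path(datadir, "markers_14c.csv")
  c14 <- if (file.exists(c14_path)) {
    utils::read.csv(c14_path, colClasses = c(site_id = "character"))
  } else NULL
  posteriors <- list()
  for (i in seq_along(focal_ids)) {
    sid <- focal_ids[i]
    ppath <- file.path(datadir, paste0("profile_", sid, ".csv"))
    if (!file.exists(ppath)) next
    prof <- utils::read.csv(ppath)
    cy <- sites$collection_year[sites$site_id == sid][1]
    mks <- detect_markers(prof, cy)
    if (!is.null(c14)) {
      extra <- c14[c14$site_id == sid, c("depth_cm", "calendar_year",
                                         "sd_years", "kind")]
      mks <- rbind(mks, extra)
    }
    posteriors[[sid]] <- fit_age_depth(
      prof, mks, collection_year = cy, mcmc = mcmc,
      seed = seeds[1] + i)
    logf("chronology: %s mean accretion %.3f cm/yr", sid,
         mean(posteriors[[sid]]$accretion_draws))
  }
  if (!length(posteriors)) stop("no focal profiles found", call. = FALSE)
  composite <- composite_chronology(posteriors)
  utils::write.csv(as.data.frame(composite),
                   file.path(outdir, "composite_chronology.csv"),
                   row.names = FALSE)
  stage_times$chronology <- tic() - t0

  # --- era binning + isoscapes --------------------------------------
  t0 <- tic()
  dated <- apply_chronology(composite, cores, eras)
  utils::write.csv(dated, file.path(outdir, "dated_samples.csv"),
                   row.names = FALSE)
  iso_summ <- list()
  for (var in c("d15N", "d13C", "cn_molar")) {
    maps <- build_isoscapes(dated, sites, variable = var, eras = eras,
                            cell_size = cell_size,
                            force_family = "spherical",
                            seed = seeds[2])
    for (er in names(maps)) {
      tag <- paste0(var, "_", gsub("[^0-9A-Za-z]", "_", er))
      write_isoscape_asc(maps[[er]],
                         file.path(outdir, paste0("iso_", tag, ".asc")))
      iso_summ[[length(iso_summ) + 1]] <- data.frame(
        variable = var, era = er,
        mean = isoscape_mean(maps[[er]]),
        n_sites = nrow(maps[[er]]$site_values),
        cv_rmse = maps[[er]]$cv_rmse)
    }
    logf("isoscape: %s mapped for %d eras", var, length(maps))
  }
  iso_summ <- do.call(rbind, iso_summ)
  utils::write.csv(iso_summ, file.path(outdir, "isoscape_summary.csv"),
                   row.names = FALSE)
  stage_times$isoscape <- tic() - t0

  # --- change-point decomposition -----------------------------------
  t0 <- tic()
  series <- utils::read.csv(file.path(datadir, "series.csv"),
                            colClasses = c(site_id = "character"))
  wq_path <- file.path(datadir, "water_quality.csv")
  wq <- if (file.exists(wq_path)) {
    utils::read.csv(wq_path, colClasses = c(station_id = "character"))
  } else {
    warning("no water-quality table; pairing section omitted",
            call. = FALSE)
    NULL
  }
  difabs <- list(); bars <- list(); pairing <- list()
  for (sid in unique(series$site_id)) {
    s <- series[series$site_id == sid, c("year", "value")]
    dec <- decompose_series(s)
    da <- dec$dif_abs
    difabs[[sid]] <- data.frame(
      site_id = sid, DIF = da$DIF, ABS = da$ABS,
      change_year = dec$change_year,
      p_value = dec$pettitt$p_value,
      step_offset = dec$step_offset,
      slope_after = dec$slope_after,
      attributed_to_inlet = dec$step_attributed_to_inlet,
      fraction_before_1988 = fraction_before(dec, 1988))
    bars[[sid]] <- data.frame(site_id = sid,
                              step_component = dec$step_component,
                              trend_component = dec$trend_component)
    if (!is.null(wq)) {
      pw <- pair_with_water_quality(s, wq, paste0("W_", sid))
      pairing[[sid]] <- data.frame(site_id = sid, r_no3 = pw$r_no3,
                                   r_salinity = pw$r_salinity,
                                   n_years = pw$n)
    }
  }
  difabs <- do.call(rbind, difabs)
  bars <- do.call(rbind, bars)
  utils::write.csv(difabs, file.path(outdir, "dif_abs.csv"),
                   row.names = FALSE)
  utils::write.csv(bars, file.path(outdir, "step_trend_components.csv"),
                   row.names = FALSE)
  stage_times$changepoint <- tic() - t0

  # --- nitrogen budget ----------------------------------------------
  t0 <- tic()
  history <- utils::read.csv(file.path(datadir, "watershed.csv"))
  params <- if (is.null(nlm_params_path)) nlm_params() else
    nlm_params(nlm_params_path)
  budget <- nlm_budget(history, params)
  utils::write.csv(as.data.frame(budget),
                   file.path(outdir, "nlm_budget.csv"),
                   row.names = FALSE)
  stage_times$nlm <- tic() - t0
  logf("nlm: dominant source 2010 = %s",
       utils::tail(dominant_source(budget), 1))

  report <- list(
    seed = seed,
    n_sites = nrow(sites),
    n_focal = length(focal_ids),
    chronology = list(
      cores = names(posteriors),
      mean_accretion_cm_yr = vapply(
        posteriors, function(p) mean(p$accretion_draws), 0),
      composite_year_at_surface = composite$mean_year[1],
      composite_year_at_base =
        composite$mean_year[nrow(composite)]),
    isoscapes = iso_summ,
    dif_abs = difabs,
    step_trend_components = bars,
    water_quality_pairing = if (length(pairing))
      do.call(rbind, pairing) else NULL,
    nlm_budget = as.data.frame(budget),
    manifest = list.files(outdir))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (st in names(stage_times)) {
    logf("stage %s: %.1f s", st, stage_times[[st]])
  }
  invisible(report)
}
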