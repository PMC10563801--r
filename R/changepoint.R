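# Step-change analysis of annual site series: the Pettitt test, split
# regression around the change year, step/trend decomposition with
# attribution to the 1946 inlet construction, DIF/ABS summaries, and
# pairing with monitoring-era water quality.

#' Pettitt change-point test
#'
#' The rank-based statistic U_t = sum_{i <= t} sum_{j > t} sign(x_j -
#' x_i) for t = 1..n-1 (computed via the midrank identity U_t =
#' 2 * sum_{i <= t} r_i - t * (n + 1), which equals the sign double sum
#' including under ties), K = max |U_t|, change point at the argmax
#' (earliest t on ties), and the standard approximate significance
#' p = min(1, 2 * exp(-6 K^2 / (n^3 + n^2))).
#'
#' @param series data.frame with year, value (no missing values; see
#'   [interpolate_series()]).
#' @return list of class `pettitt_result`: change_index, change_year,
#'   K, U (the full trace), p_value, n, degenerate (TRUE for a constant
#'   series, where the change year is undefined).
#' @export
pettitt <- function(series) {
  x <- series$value
  n <- length(x)
  if (n < 10) stop("need n >= 10 points", call. = FALSE)
  if (anyNA(x)) stop("series has missing values; interpolate first",
                     call. = FALSE)
  r <- rank(x)
  # midrank identity: sum_{i<=t} sum_j sign(x_i - x_j) = 2*sum r_i - t(n+1)
  U <- seq_len(n - 1) * (n + 1) - 2 * cumsum(r)[-n]
  K <- max(abs(U))
  p <- min(1, 2 * exp(-6 * K^2 / (n^3 + n^2)))
  degenerate <- K == 0
  ci <- if (degenerate) NA_integer_ else which.max(abs(U))
  structure(list(
    change_index = ci,
    change_year = if (degenerate) NA_real_ else series$year[ci],
    K = K, U = U, p_value = if (degenerate) 1 else p,
    n = n, degenerate = degenerate),
    class = "pettitt_result")
}

#' @export
print.pettitt_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Pettitt: constant series, no change point (K = 0, p = 1)\n")
  } else {
    cat(sprintf("Pettitt: change after %s (K = %d, p = %.4g, n = %d)\n",
                format(x$change_year), x$K, x$p_value, x$n))
  }
  invisible(x)
}

#' Fill missing years of an annual series by linear interpolation
#'
#' @param series data.frame with year, value (NA values allowed).
#' @return series with NA values interpolated; attribute
#'   `interpolated` gives the filled years.
#' @export
interpolate_series <- function(series) {
  miss <- is.na(series$value)
  if (any(miss)) {
    series$value <- stats::approx(series$year[!miss],
                                  series$value[!miss], series$year,
                                  rule = 2)$y
  }
  attr(series, "interpolated") <- series$year[miss]
  series
}

#' Split regression around a change year
#'
#' Ordinary least squares fitted separately to the observations before
#' the change year (year < change_year) and from it onward. The step
#' offset is the gap between the two fits evaluated at the change year:
#' (after-fit prediction) - (before-fit prediction), both at
#' `change_year`.
#'
#' @param series data.frame with year, value.
#' @param change_year calendar year of the split.
#' @return list of class `decomposition`: change_year, step_offset,
#'   slope_before, slope_after (with `se_before`, `se_after`), the two
#'   lm fits, and `fitted_at(year)` evaluating the piecewise model.
#' @export
split_regression <- function(series, change_year) {
  before <- series[series$year < change_year, , drop = FALSE]
  after <- series[series$year >= change_year, , drop = FALSE]
  fit_side <- function(d) {
    if (nrow(d) < 3) return(NULL)
    stats::lm(value ~ year, data = d)
  }
  fb <- fit_side(before)
  fa <- fit_side(after)
  pred <- function(fit, yr) {
    unname(stats::predict(fit, newdata = data.frame(year = yr)))
  }
  offset <- if (!is.null(fb) && !is.null(fa)) {
    pred(fa, change_year) - pred(fb, change_year)
  } else NA_real_
  slope_se <- function(fit) {
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    s <- summary(fit)$coefficients
    c(s["year", "Estimate"], s["year", "Std. Error"])
  }
  sb <- slope_se(fb); sa <- slope_se(fa)
  fitted_at <- function(yr) {
    out <- rep(NA_real_, length(yr))
    bef <- yr < change_year
    if (!is.null(fb)) out[bef] <- pred(fb, yr[bef])
    if (!is.null(fa)) out[!bef] <- pred(fa, yr[!bef])
    out
  }
  structure(list(
    change_year = change_year, step_offset = offset,
    slope_before = sb[1], se_before = sb[2],
    slope_after = sa[1], se_after = sa[2],
    fit_before = fb, fit_after = fa, fitted_at = fitted_at,
    years = range(series$year)),
    class = "decomposition")
}

#' Detect and decompose a step + trend in an annual series
#'
#' Runs the Pettitt test; if significant at `alpha`, fits
#' [split_regression()] at the detected change year and reports the step
#' and trend contributions to the fitted total change (step_offset, and
#' slope_after times the years remaining after the change). The step is
#' attributed to the harbor-inlet construction when the change year
#' falls within `harbor_year +/- harbor_tolerance`. If the change point
#' is not significant, a single full-series trend is returned with
#' `significant = FALSE`.
#'
#' @param series data.frame with year, value.
#' @param harbor_year calendar year of the inlet construction (1946).
#' @param harbor_tolerance attribution window, years (10).
#' @param alpha significance level for the Pettitt test.
#' @return list of class `decomposition` (as [split_regression()]) with
#'   added fields: pettitt, significant, step_attributed_to_inlet,
#'   step_component, trend_component, dif_abs.
#' @export
decompose_series <- function(series, harbor_year = 1946,
                             harbor_tolerance = 10, alpha = 0.05) {
  series <- interpolate_series(series)
  pt <- pettitt(series)
  significant <- !pt$degenerate && pt$p_value < alpha
  if (significant) {
    # split AFTER the change index: years > series$year[ci] are "after"
    cy <- series$year[pt$change_index + 1]
    dec <- split_regression(series, cy)
    end_year <- max(series$year)
    step_comp <- dec$step_offset
    trend_comp <- if (!is.na(dec$slope_after)) {
      dec$slope_after * (end_year - cy)
    } else NA_real_
    attributed <- abs(cy - harbor_year) <= harbor_tolerance
  } else {
    fit <- stats::lm(value ~ year, data = series)
    s <- summary(fit)$coefficients
    dec <- structure(list(
      change_year = NA_real_, step_offset = NA_real_,
      slope_before = NA_real_, se_before = NA_real_,
      slope_after = s["year", "Estimate"],
      se_after = s["year", "Std. Error"],
      fit_before = NULL, fit_after = fit,
      fitted_at = function(yr) {
        unname(stats::predict(fit, newdata = data.frame(year = yr)))
      },
      years = range(series$year)), class = "decomposition")
    step_comp <- 0
    trend_comp <- dec$slope_after * diff(range(series$year))
    attributed <- FALSE
  }
  dec$pettitt <- pt
  dec$significant <- significant
  dec$step_attributed_to_inlet <- attributed
  dec$step_component <- step_comp
  dec$trend_component <- trend_comp
  dec$dif_abs <- dif_abs(series)
  dec
}

#' DIF and ABS summaries of a series
#'
#' ABS is the value at the end year; DIF is the end value minus the
#' start value. If an exact endpoint year is absent, the nearest year
#' within `tolerance` is used and flagged.
#'
#' @param series data.frame with year, value.
#' @param start_year,end_year summary endpoints (1850 and 2010).
#' @param tolerance maximum distance (years) to a substitute endpoint.
#' @return list: DIF, ABS, start_year_used, end_year_used, exact.
#' @export
dif_abs <- function(series, start_year = 1850, end_year = 2010,
                    tolerance = 5) {
  pick <- function(target) {
    d <- abs(series$year - target)
    i <- which.min(d)
    if (d[i] > tolerance) {
      stop("no observation within ", tolerance, " years of ", target,
           call. = FALSE)
    }
    i
  }
  i0 <- pick(start_year); i1 <- pick(end_year)
  list(DIF = series$value[i1] - series$value[i0],
       ABS = series$value[i1],
       start_year_used = series$year[i0],
       end_year_used = series$year[i1],
       exact = series$year[i0] == start_year &&
         series$year[i1] == end_year)
}

#' Fraction of the fitted total change occurring before a year
#'
#' (fitted(year) - fitted(start)) / (fitted(end) - fitted(start)),
#' clipped to [0, 1]. Used to ask how much of the reconstructed change
#' predates the onset of water-quality monitoring (1988).
#'
#' @param decomposition a `decomposition` from [decompose_series()] or
#'   [split_regression()].
#' @param year reference year (default 1988).
#' @return numeric fraction in [0, 1]; NA with a warning when the fitted
#'   total change is zero.
#' @export
fraction_before <- function(decomposition, year = 1988) {
  f <- decomposition$fitted_at
  y0 <- decomposition$years[1]
  y1 <- decomposition$years[2]
  total <- f(y1) - f(y0)
  if (!is.finite(total) || total == 0) {
    warning("fitted total change is zero; fraction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  min(max((f(year) - f(y0)) / total, 0), 1)
}

#' Pair a sediment series with annual mean water quality
#'
#' Joins the sediment values with station-year means of nitrate and
#' salinity ([annual_mean_water_quality()]) over the overlapping years
#' and reports Pearson correlations.
#'
#' @param series data.frame with year, value (sediment d15N).
#' @param wq_records water-quality records (station_id, date, no3,
#'   salinity).
#' @param station station identifier paired with this core site.
#' @param years years to attempt (default 1990:2010).
#' @return list: `table` (year, value, no3, salinity, n_months),
#'   `r_no3`, `r_salinity`, `n` (overlapping years). Correlations are NA
#'   (flagged via `constant_no3`) when the nitrate series is constant.
#' @export
pair_with_water_quality <- function(series, wq_records, station,
                                    years = 1990:2010) {
  rows <- lapply(years, function(y) {
    wq <- annual_mean_water_quality(wq_records, station, y)
    i <- match(y, series$year)
    data.frame(year = y,
               value = if (is.na(i)) NA_real_ else series$value[i],
               no3 = wq$no3, salinity = wq$salinity,
               n_months = wq$n_months)
  })
  tab <- do.call(rbind, rows)
  ok <- stats::complete.cases(tab[, c("value", "no3")])
  n <- sum(ok)
  constant_no3 <- n >= 2 && stats::sd(tab$no3[ok]) == 0
  r_no3 <- if (n >= 3 && !constant_no3) {
    stats::cor(tab$value[ok], tab$no3[ok])
  } else NA_real_
  oks <- stats::complete.cases(tab[, c("value", "salinity")])
  r_sal <- if (sum(oks) >= 3 && stats::sd(tab$salinity[oks]) > 0) {
    stats::cor(tab$value[oks], tab$salinity[oks])
  } else NA_real_
  list(table = tab, r_no3 = r_no3, r_salinity = r_sal, n = n,
       constant_no3 = constant_no3)
}
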