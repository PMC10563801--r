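# Geostatistics: empirical semivariograms (Matheron estimator), weighted
# least-squares variogram fitting for the spherical, circular,
# exponential, Gaussian and linear families, ordinary and universal
# kriging (polynomial drift orders 0-2), seeded holdout cross-validation
# for family selection, and era-binned isoscape construction.

.VGM_FAMILIES <- c("spherical", "circular", "exponential", "gaussian",
                   "linear_drift1", "linear_drift2")

# Semivariance gamma(h) for each family. `linear` has no sill: psill is
# the slope per unit lag. gamma(0) = 0 always; the nugget applies for
# h > 0 (measurement-scale discontinuity).
.vgm_gamma <- function(h, family, nugget, psill, range) {
  g <- switch(family,
    spherical = {
      u <- pmin(h / range, 1)
      psill * (1.5 * u - 0.5 * u^3)
    },
    circular = {
      u <- pmin(h / range, 1)
      psill * (1 - (2 / pi) * (acos(u) - u * sqrt(pmax(1 - u^2, 0))))
    },
    exponential = psill * (1 - exp(-3 * h / range)),
    gaussian = psill * (1 - exp(-3 * (h / range)^2)),
    linear_drift1 = ,
    linear_drift2 = ,
    linear = psill * h / range,
    stop("unknown variogram family: ", family, call. = FALSE)
  )
  out <- nugget + g
  out[h == 0] <- 0
  out
}

#' Evaluate a fitted variogram model
#'
#' Returns the model semivariance at the given lags. At h = 0 the value
#' is the nugget (the microscale discontinuity); the kriging solver
#' itself uses the measurement-free limit gamma(0) = 0 on the system
#' diagonal, which is what makes kriging an exact interpolator.
#'
#' @param model a `variogram_model`.
#' @param h lags (m).
#' @return semivariances.
#' @export
vgm_eval <- function(model, h) {
  out <- .vgm_gamma(h, model$family, model$nugget, model$psill,
                    model$range)
  out[h == 0] <- model$nugget
  out
}

#' Empirical semivariogram (Matheron estimator)
#'
#' gamma_hat(h) = 1/(2 N(h)) * sum over point pairs in lag bin h of
#' (z_i - z_j)^2.
#'
#' @param points data.frame with x, y.
#' @param values numeric vector, one per point.
#' @param n_bins number of lag bins.
#' @param max_lag maximum lag (default: half the maximum pairwise
#'   distance).
#' @return data.frame of class `empirical_variogram`: lag (bin centre),
#'   gamma, n_pairs; empty bins are dropped.
#' @export
empirical_variogram <- function(points, values, n_bins = 12,
                                max_lag = NULL) {
  n <- nrow(points)
  if (n < 2) stop("need >= 2 points", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  d <- as.matrix(stats::dist(points[, c("x", "y")]))
  iu <- upper.tri(d)
  h <- d[iu]
  if (all(h == 0)) stop("all points coincident; no valid lags",
                        call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(h) / 2
  sq <- (outer(values, values, "-")^2)[iu]
  keep <- h > 0 & h <= max_lag
  h <- h[keep]; sq <- sq[keep]
  edges <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- findInterval(h, edges, rightmost.closed = TRUE)
  gam <- tapply(sq, bin, function(s) sum(s) / (2 * length(s)))
  npairs <- tapply(sq, bin, length)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- as.integer(names(gam))
  structure(
    data.frame(lag = centres[idx], gamma = as.numeric(gam),
               n_pairs = as.integer(npairs)),
    max_lag = max_lag, class = c("empirical_variogram", "data.frame"))
}

# Moment-based starting values for the WLS fit.
.vgm_init <- function(emp) {
  sill0 <- max(mean(emp$gamma[emp$lag > stats::median(emp$lag)]),
               max(emp$gamma) * 0.5, 1e-8)
  nug0 <- max(min(emp$gamma) * 0.5, 0)
  range0 <- max(emp$lag[which.max(emp$gamma >= 0.95 * sill0)],
                max(emp$lag) / 3)
  c(nugget = nug0, psill = max(sill0 - nug0, 1e-8), range = range0)
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises sum over lag bins of N(h) * (gamma_hat(h) - gamma(h))^2 with
#' box constraints nugget >= 0, partial sill >= 0, range > 0. If the
#' optimiser fails, the moment-based initial estimate is returned with
#' `fallback = TRUE`.
#'
#' @param emp an [empirical_variogram()].
#' @param family one of `r paste(.VGM_FAMILIES, collapse = ", ")` (the
#'   linear families fit a slope + nugget line; their drift order only
#'   matters at kriging time).
#' @return list of class `variogram_model`: family, nugget, psill, range,
#'   drift_order, rss, fallback.
#' @export
fit_variogram <- function(emp, family = "spherical") {
  family <- match.arg(family, .VGM_FAMILIES)
  if (nrow(emp) < 3) stop("need >= 3 non-empty lag bins", call. = FALSE)
  drift <- switch(family, linear_drift1 = 1L, linear_drift2 = 2L, 0L)
  if (all(emp$gamma == 0)) {
    return(structure(list(family = family, nugget = 0, psill = 0,
                          range = max(emp$lag), drift_order = drift,
                          rss = 0, fallback = FALSE),
                     class = "variogram_model"))
  }
  obj <- function(p) {
    g <- .vgm_gamma(emp$lag, family, p[1], p[2], p[3])
    sum(emp$n_pairs * (emp$gamma - g)^2)
  }
  init <- .vgm_init(emp)
  fit <- tryCatch(
    stats::optim(init, obj, method = "L-BFGS-B",
                 lower = c(0, 0, max(emp$lag) * 1e-3),
                 upper = c(Inf, Inf, max(emp$lag) * 10)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    p <- init
    rss <- obj(init)
    fallback <- TRUE
  } else {
    p <- fit$par
    rss <- fit$value
    fallback <- FALSE
  }
  structure(list(family = family, nugget = unname(p[1]),
                 psill = unname(p[2]), range = unname(p[3]),
                 drift_order = drift, rss = rss, fallback = fallback),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s (nugget %.4g, psill %.4g, range %.4g",
              x$family, x$nugget, x$psill, x$range))
  if (x$drift_order > 0) cat(", drift order", x$drift_order)
  cat(")\n")
  invisible(x)
}

# Drift basis: monomials of (x, y) up to the given order.
.drift_basis <- function(x, y, order) {
  out <- cbind(rep(1, length(x)))
  if (order >= 1) out <- cbind(out, x, y)
  if (order >= 2) out <- cbind(out, x^2, x * y, y^2)
  out
}

#' Ordinary / universal kriging
#'
#' Solves the kriging system at each target: weights minimise the
#' prediction variance subject to unbiasedness constraints (weights sum
#' to 1 for ordinary kriging; additionally orthogonal to the polynomial
#' drift basis for universal kriging). Duplicate data coordinates are
#' averaged before solving.
#'
#' @param points data.frame of data coordinates (x, y).
#' @param values numeric data values.
#' @param model a `variogram_model` (its `drift_order` selects ordinary
#'   vs universal kriging).
#' @param targets data.frame of prediction coordinates (x, y).
#' @return list: `pred` and `var` (kriging variance), one per target,
#'   plus `weights` (targets x data matrix).
#' @export
krige <- function(points, values, model, targets) {
  xy <- as.matrix(points[, c("x", "y")])
  key <- paste(xy[, 1], xy[, 2])
  if (anyDuplicated(key)) {
    ord_keys <- unique(key)
    vals <- vapply(ord_keys, function(k) mean(values[key == k]), 0)
    xy <- xy[match(ord_keys, key), , drop = FALSE]
    values <- unname(vals)
  }
  n <- nrow(xy)
  drift <- model$drift_order
  p <- ncol(.drift_basis(0, 0, drift))
  if (n < p + 1) {
    stop("need at least ", p + 1, " distinct points for drift order ",
         drift, call. = FALSE)
  }
  # degenerate zero-variance model (e.g. fitted to a constant field):
  # any convex weights are exact; use the equal-weight limit
  if (model$nugget == 0 && model$psill == 0) {
    nt <- nrow(targets)
    return(list(pred = rep(mean(values), nt), var = rep(0, nt),
                weights = matrix(1 / n, nt, n)))
  }
  G <- .vgm_gamma(as.matrix(stats::dist(xy)), model$family,
                  model$nugget, model$psill, model$range)
  F_ <- .drift_basis(xy[, 1], xy[, 2], drift)
  A <- rbind(cbind(G, F_), cbind(t(F_), matrix(0, p, p)))
  tx <- as.matrix(targets[, c("x", "y")])
  d0 <- sqrt(outer(xy[, 1], tx[, 1], "-")^2 +
             outer(xy[, 2], tx[, 2], "-")^2)
  g0 <- .vgm_gamma(d0, model$family, model$nugget, model$psill,
                   model$range)
  f0 <- t(.drift_basis(tx[, 1], tx[, 2], drift))
  B <- rbind(g0, f0)
  sol <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e), call. = FALSE)
  })
  W <- sol[seq_len(n), , drop = FALSE]
  Mu <- sol[-seq_len(n), , drop = FALSE]
  pred <- drop(crossprod(W, values))
  kvar <- colSums(W * g0) + colSums(Mu * f0)
  kvar <- pmax(kvar, 0)
  list(pred = pred, var = kvar, weights = t(W))
}

#' Select a variogram family by seeded holdout cross-validation
#'
#' A seeded random subset of the points (default 15%) is held out once.
#' Each candidate family is fitted to the empirical variogram of the
#' retained points; every held-out point is then predicted leave-one-out
#' from all other points under that model, and the family with the
#' smallest RMSE wins. Ties are broken by the fixed family order, with
#' spherical first. Families whose fit fails are excluded and flagged.
#'
#' @param points data.frame (x, y).
#' @param values numeric data values.
#' @param families candidate families, tried in order.
#' @param holdout_fraction fraction of points held out (default 0.15).
#' @param seed RNG seed for the holdout draw.
#' @param n_bins lag bins for the empirical variograms.
#' @return list: `best` (family name), `rmse` (data.frame family, rmse,
#'   failed), `holdout` (indices held out), `models` (fitted models).
#' @export
select_variogram <- function(points, values,
                             families = c("spherical", "circular",
                                          "exponential", "gaussian"),
                             holdout_fraction = 0.15, seed = 1,
                             n_bins = 12) {
  n <- nrow(points)
  m <- max(2, round(n * holdout_fraction))
  if (m >= n - 2) stop("too few points for a ", holdout_fraction,
                       " holdout", call. = FALSE)
  hold <- .with_seed(seed, sort(sample.int(n, m)))
  retained <- setdiff(seq_len(n), hold)
  emp <- empirical_variogram(points[retained, , drop = FALSE],
                             values[retained], n_bins = n_bins)
  rmse <- rep(NA_real_, length(families))
  failed <- rep(FALSE, length(families))
  models <- vector("list", length(families))
  for (fi in seq_along(families)) {
    fam <- families[fi]
    mod <- tryCatch(fit_variogram(emp, fam), error = function(e) NULL)
    if (is.null(mod)) { failed[fi] <- TRUE; next }
    models[[fi]] <- mod
    errs <- tryCatch(vapply(hold, function(i) {
      kr <- krige(points[-i, , drop = FALSE], values[-i], mod,
                  points[i, , drop = FALSE])
      kr$pred - values[i]
    }, 0), error = function(e) NULL)
    if (is.null(errs)) { failed[fi] <- TRUE; next }
    rmse[fi] <- sqrt(mean(errs^2))
  }
  tab <- data.frame(family = families, rmse = rmse, failed = failed)
  ok <- which(!failed)
  if (!length(ok)) stop("every candidate family failed to fit",
                        call. = FALSE)
  best <- families[ok[which.min(rmse[ok])]]
  list(best = best, rmse = tab, holdout = hold, models = models)
}

# Convex hull of the sites, as a closed polygon matrix.
.hull_polygon <- function(points) {
  idx <- grDevices::chull(points$x, points$y)
  cbind(points$x[idx], points$y[idx])
}

# Distance from points to a polygon boundary (minimum over edges).
.dist_to_polygon <- function(px, py, poly) {
  k <- nrow(poly)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(k)) {
    j <- if (i == k) 1 else i + 1
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    dd <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    dmin <- pmin(dmin, dd)
  }
  dmin
}

#' Build era-binned isoscape maps
#'
#' For each era: the per-site value is the mean of that site's dated
#' samples falling in the era (samples must carry an `era` column from
#' [apply_chronology()]); a variogram family is selected by
#' [select_variogram()] (or forced, e.g. spherical for cross-era
#' comparability); the surface is kriged onto a regular grid masked to
#' the convex hull of the contributing sites buffered by one cell. Eras
#' with fewer than 4 sites are skipped with a warning.
#'
#' @param samples dated samples: data.frame with site_id, era and the
#'   value column named by `variable`.
#' @param sites data.frame with site_id, x, y.
#' @param variable one of "d15N", "d13C", "cn_molar".
#' @param eras era bins (rows define which maps are attempted).
#' @param cell_size grid cell size, m (default 50).
#' @param force_family if non-NULL, use this family for every era.
#' @param families candidates for selection when not forced.
#' @param seed seed for the cross-validation holdout.
#' @return named list of `isoscape` objects (one per mapped era), each
#'   with grid vectors `xs`, `ys`, matrices `pred` and `var` (ny x nx),
#'   logical `mask`, the fitted `model`, `cv_rmse`, and the per-site
#'   era values in `site_values`.
#' @export
build_isoscapes <- function(samples, sites, variable = "d15N",
                            eras = era_bins(), cell_size = 50,
                            force_family = NULL,
                            families = c("spherical", "circular",
                                         "exponential", "gaussian"),
                            seed = 1) {
  stopifnot(variable %in% names(samples), "era" %in% names(samples))
  out <- list()
  for (er in eras$label) {
    sub <- samples[!is.na(samples$era) & samples$era == er &
                     !is.na(samples[[variable]]), , drop = FALSE]
    if (!nrow(sub)) next
    agg <- stats::aggregate(sub[[variable]],
                            by = list(site_id = sub$site_id), FUN = mean)
    names(agg)[2] <- "value"
    pts <- merge(agg, sites[, c("site_id", "x", "y")], by = "site_id")
    if (nrow(pts) < 4) {
      warning("era '", er, "' has < 4 sites with data; skipped",
              call. = FALSE)
      next
    }
    cv_rmse <- NA_real_
    if (is.null(force_family)) {
      sel <- select_variogram(pts, pts$value, families = families,
                              seed = seed)
      fam <- sel$best
      cv_rmse <- min(sel$rmse$rmse, na.rm = TRUE)
    } else {
      fam <- force_family
    }
    emp <- empirical_variogram(pts, pts$value)
    model <- fit_variogram(emp, fam)
    xs <- seq(min(pts$x), max(pts$x), by = cell_size)
    ys <- seq(min(pts$y), max(pts$y), by = cell_size)
    gridpts <- expand.grid(x = xs, y = ys)
    poly <- .hull_polygon(pts)
    inside <- if (nrow(poly) >= 3) {
      mgcv::in.out(rbind(poly, poly[1, ]),
                   as.matrix(gridpts[, c("x", "y")]))
    } else rep(TRUE, nrow(gridpts))
    near <- .dist_to_polygon(gridpts$x, gridpts$y, poly) <= cell_size
    mask <- inside | near
    kr <- krige(pts, pts$value, model, gridpts[mask, , drop = FALSE])
    # expand.grid varies x fastest: fill row-wise (ny x nx) matrices
    pred_vec <- rep(NA_real_, nrow(gridpts)); var_vec <- pred_vec
    pred_vec[mask] <- kr$pred
    var_vec[mask] <- kr$var
    pred <- matrix(pred_vec, length(ys), length(xs), byrow = TRUE)
    kvar <- matrix(var_vec, length(ys), length(xs), byrow = TRUE)
    maskm <- matrix(mask, length(ys), length(xs), byrow = TRUE)
    out[[er]] <- structure(list(
      variable = variable, era = er, xs = xs, ys = ys,
      pred = pred, var = kvar, mask = maskm, model = model,
      cv_rmse = cv_rmse, site_values = pts),
      class = "isoscape")
  }
  out
}

#' @export
print.isoscape <- function(x, ...) {
  cat(sprintf("isoscape: %s, era %s, %d x %d grid, %s model\n",
              x$variable, x$era, length(x$xs), length(x$ys),
              x$model$family))
  cat(sprintf("  masked mean %.3f (range %.3f to %.3f)\n",
              mean(x$pred[x$mask]), min(x$pred[x$mask]),
              max(x$pred[x$mask])))
  invisible(x)
}

#' Mean predicted value of an isoscape over its masked domain
#' @param iso an `isoscape`.
#' @return numeric scalar.
#' @export
isoscape_mean <- function(iso) mean(iso$pred[iso$mask])

#' Write an isoscape as an ESRI ASCII grid with a JSON sidecar
#'
#' @param iso an `isoscape`.
#' @param path output `.asc` path; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_isoscape_asc <- function(iso, path) {
  nr <- length(iso$ys); nc <- length(iso$xs)
  cell <- iso$xs[2] - iso$xs[1]
  m <- iso$pred
  m[!iso$mask] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", iso$xs[1] - cell / 2),
    paste("yllcorner", iso$ys[1] - cell / 2),
    paste("cellsize", cell), "NODATA_value -9999"), con)
  for (i in rev(seq_len(nr))) {  # ASCII grids run north to south
    writeLines(paste(formatC(m[i, ], digits = 8, format = "g"),
                     collapse = " "), con)
  }
  side <- list(variable = iso$variable, era = iso$era,
               family = iso$model$family, nugget = iso$model$nugget,
               psill = iso$model$psill, range = iso$model$range,
               cv_rmse = iso$cv_rmse)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
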