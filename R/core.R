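# Shared domain types, isotope/stoichiometry conversions and table I/O.

# IUPAC standard atomic weights; used for weight%% -> molar conversion.
.ATOMIC_WEIGHT_C <- 12.011
.ATOMIC_WEIGHT_N <- 14.007

#' Convert an isotope abundance ratio to delta (per mil) notation
#'
#' delta = (R_sample / R_standard - 1) * 1000, the per-mil deviation of a
#' sample's heavy/light isotope abundance ratio from a reference standard
#' (atmospheric N2 for nitrogen, VPDB for carbon). Standards have delta = 0
#' by definition.
#'
#' @param r_sample isotope abundance ratio of the sample (heavy/light).
#' @param r_standard isotope abundance ratio of the standard; must be > 0.
#' @return delta value in per mil.
#' @seealso [ratio_from_delta()] for the inverse transform.
#' @export
#' @examples
#' delta_value(0.0036782, 0.0036765)
delta_value <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("`r_standard` must be a positive finite ratio", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Recover a sample isotope ratio from a delta value
#'
#' Inverse of [delta_value()]: R_sample = R_standard * (1 + delta/1000).
#'
#' @param delta delta value in per mil.
#' @param r_standard isotope abundance ratio of the standard; must be > 0.
#' @return the sample abundance ratio.
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("`r_standard` must be a positive finite ratio", call. = FALSE)
  }
  r_standard * (1 + delta / 1000)
}

#' Molar carbon-to-nitrogen ratio from weight percent
#'
#' Converts elemental weight percentages to the molar stoichiometric ratio
#' (C/12.011) / (N/14.007). Vectorised; returns NA where either input is NA.
#'
#' @param c_pct carbon, weight percent (>= 0).
#' @param n_pct nitrogen, weight percent (> 0 where defined).
#' @return dimensionless molar C/N ratio.
#' @export
#' @examples
#' cn_molar(12.011, 14.007)  # one mole of each -> 1
cn_molar <- function(c_pct, n_pct) {
  bad <- !is.na(n_pct) & n_pct <= 0
  if (any(bad)) {
    stop("`n_pct` must be > 0 for a defined C/N ratio", call. = FALSE)
  }
  (c_pct / .ATOMIC_WEIGHT_C) / (n_pct / .ATOMIC_WEIGHT_N)
}

#' Era bins used to date depth intervals
#'
#' Builds a set of contiguous half-open calendar bins [start, end). The
#' default set is the six mapping eras used throughout the package:
#' ca. 1726-1839, 1839-1885, 1885-1951, 1951-1963, 1963-1981 and 1981-2010
#' (the last bin closes just after 2010 so that year is included).
#'
#' @param breaks increasing vector of bin edges (calendar years).
#' @param labels optional labels; default "start-end".
#' @return data.frame of class `era_bins` with columns label, start_year,
#'   end_year.
#' @export
era_bins <- function(breaks = c(1726, 1839, 1885, 1951, 1963, 1981, 2011),
                     labels = NULL) {
  if (length(breaks) < 2 || is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  start <- breaks[-length(breaks)]
  end <- breaks[-1]
  if (is.null(labels)) {
    # label by the covered years; the terminal open edge prints as end - 1
    shown_end <- ifelse(end == breaks[length(breaks)], end - 1, end)
    labels <- paste0(start, "-", shown_end)
  }
  structure(
    data.frame(label = labels, start_year = start, end_year = end,
               stringsAsFactors = FALSE),
    class = c("era_bins", "data.frame")
  )
}

#' Assign calendar years to era bins
#'
#' @param years numeric calendar years.
#' @param eras an `era_bins` table from [era_bins()].
#' @return character vector of era labels; NA where a year falls outside
#'   every bin.
#' @export
assign_era <- function(years, eras = era_bins()) {
  idx <- findInterval(years, c(eras$start_year, eras$end_year[nrow(eras)]))
  lab <- rep(NA_character_, length(years))
  ok <- idx >= 1 & idx <= nrow(eras) & !is.na(years)
  lab[ok] <- eras$label[idx[ok]]
  lab
}

.CORE_TABLE_COLS <- c("site_id", "x", "y", "top_cm", "bottom_cm",
                      "d15N", "d13C", "c_pct", "n_pct")

#' Read a core-sample table
#'
#' Reads a comma-delimited UTF-8 table of per-interval core measurements
#' with required header columns site_id, x, y, top_cm, bottom_cm, d15N,
#' d13C, c_pct, n_pct. Empty cells are missing values. The molar C/N ratio
#' is derived (`cn_molar` column) wherever n_pct > 0.
#'
#' @param path file path.
#' @return data.frame of samples with a derived `cn_molar` column; the
#'   distinct sites (site_id, x, y) are attached as attribute `"sites"`.
#' @export
read_core_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site_id = "character"))
  missing_cols <- setdiff(.CORE_TABLE_COLS, names(df))
  if (length(missing_cols)) {
    stop("core table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(.CORE_TABLE_COLS, "site_id")
  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      v[v == ""] <- NA
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at row %d", cc,
                     bad[1]), call. = FALSE)
      }
      df[[cc]] <- parsed
    }
  }
  if (nrow(df)) {
    if (any(!is.na(df$top_cm) & !is.na(df$bottom_cm) &
            df$top_cm >= df$bottom_cm)) {
      stop("depth intervals must satisfy top_cm < bottom_cm", call. = FALSE)
    }
    df$cn_molar <- ifelse(!is.na(df$n_pct) & df$n_pct > 0 & !is.na(df$c_pct),
                          cn_molar(df$c_pct, pmax(df$n_pct, 1e-300)),
                          NA_real_)
  } else {
    df$cn_molar <- numeric(0)
  }
  sites <- unique(df[, c("site_id", "x", "y")])
  rownames(sites) <- NULL
  attr(df, "sites") <- sites
  df
}

#' Write a core-sample table
#'
#' Writes the documented comma-delimited core-table format; NA becomes an
#' empty field. The derived `cn_molar` column is not written (it is
#' recomputed on read). Round-trips losslessly at full double precision.
#'
#' @param samples data.frame with the core-table columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_core_table <- function(samples, path) {
  missing_cols <- setdiff(.CORE_TABLE_COLS, names(samples))
  if (length(missing_cols)) {
    stop("cannot write core table; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- samples[, .CORE_TABLE_COLS, drop = FALSE]
  for (cc in setdiff(.CORE_TABLE_COLS, "site_id")) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), "",
                        formatC(out[[cc]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Annual mean water quality for one station
#'
#' Arithmetic mean of the monthly nitrate and salinity records available
#' for a station in a calendar year, with the number of contributing
#' months. Returns NA means (not an error) when no records exist.
#'
#' @param records data.frame with columns station_id, date (Date or
#'   "YYYY-MM-DD" text), no3 (uM), salinity (ppt).
#' @param station station identifier.
#' @param year calendar year.
#' @return list with elements `no3`, `salinity`, `n_months`.
#' @export
annual_mean_water_quality <- function(records, station, year) {
  d <- as.Date(records$date)
  sel <- records$station_id == station &
    as.integer(format(d, "%Y")) == year
  sel[is.na(sel)] <- FALSE
  sub <- records[sel, , drop = FALSE]
  if (!nrow(sub)) {
    return(list(no3 = NA_real_, salinity = NA_real_, n_months = 0L))
  }
  list(no3 = mean(sub$no3, na.rm = TRUE),
       salinity = mean(sub$salinity, na.rm = TRUE),
       n_months = sum(!is.na(sub$no3)))
}

#' Export sites as GeoJSON points
#'
#' Planar coordinates are written as point coordinates; remaining columns
#' become feature properties.
#'
#' @param sites data.frame with columns site_id, x, y (and optionally more).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_geojson <- function(sites, path) {
  feat <- lapply(seq_len(nrow(sites)), function(i) {
    props <- as.list(sites[i, setdiff(names(sites), c("x", "y")),
                           drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sites$x[i], sites$y[i])),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feat)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
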