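# Watershed nitrogen-loading budget (NLM-style): decadal inputs by
# source (fertilizer, wastewater, atmospheric deposition, livestock),
# each attenuated by configurable loss/retention fractions. All
# coefficients live in a YAML parameter file; the shipped defaults are
# drawn from the published NLM literature and documented as such.

#' Read (and validate) NLM parameters
#'
#' @param path YAML parameter file; default is the parameter set shipped
#'   with the package (`inst/extdata/nlm_params.yaml`).
#' @return validated named list of class `nlm_params`.
#' @export
nlm_params <- function(path = system.file("extdata", "nlm_params.yaml",
                                          package = "paleoscape")) {
  p <- yaml::read_yaml(path)
  fracs <- c(p$septic_transmission, p$sewered_loss,
             p$fertilizer_leaching, unlist(p$deposition_retention),
             unlist(p$livestock_loss))
  if (any(fracs < 0 | fracs > 1)) {
    stop("NLM fractions must lie in [0, 1]", call. = FALSE)
  }
  rates <- c(p$per_capita_n, unlist(p$livestock_excretion))
  if (any(rates < 0)) stop("NLM rates must be >= 0", call. = FALSE)
  structure(p, class = "nlm_params")
}

#' Fertilizer nitrogen load for one decade
#'
#' max(0, rate * cultivated area - crop export) * leaching fraction: the
#' net fertilizer surplus (application minus nitrogen removed in
#' harvest) attenuated by the fraction that leaches toward the estuary.
#'
#' @param inputs one-row data.frame (or list) with fertilizer_rate
#'   (kg N ha^-1 yr^-1), area_cultivated (ha), crop_export (kg N yr^-1).
#' @param params an `nlm_params`.
#' @return kg N yr^-1.
#' @export
fertilizer_load <- function(inputs, params) {
  pmax(0, inputs$fertilizer_rate * inputs$area_cultivated -
         inputs$crop_export) * params$fertilizer_leaching
}

#' Wastewater nitrogen load for one decade
#'
#' Per-capita excretion partitioned between septic and sewered homes:
#' septic flow is attenuated by the plume transmission fraction, sewered
#' flow by (1 - treatment loss fraction).
#'
#' @param inputs one-row data.frame with population, homes_septic,
#'   homes_sewered.
#' @param params an `nlm_params`.
#' @return kg N yr^-1.
#' @export
wastewater_load <- function(inputs, params) {
  homes <- inputs$homes_septic + inputs$homes_sewered
  septic_frac <- ifelse(homes > 0, inputs$homes_septic / homes, 1)
  total_n <- inputs$population * params$per_capita_n
  total_n * (septic_frac * params$septic_transmission +
               (1 - septic_frac) * (1 - params$sewered_loss))
}

#' Atmospheric deposition nitrogen load for one decade
#'
#' Sum over land covers of deposition rate x area x (1 - retention
#' fraction of that cover).
#'
#' @param inputs one-row data.frame with atmospheric_deposition
#'   (kg N ha^-1 yr^-1) and area_cultivated, area_natural,
#'   area_impervious, area_wetland (ha).
#' @param params an `nlm_params` (list `deposition_retention` keyed by
#'   cover).
#' @return kg N yr^-1.
#' @export
atmospheric_load <- function(inputs, params) {
  ret <- params$deposition_retention
  inputs$atmospheric_deposition *
    (inputs$area_cultivated * (1 - ret$cultivated) +
       inputs$area_natural * (1 - ret$natural) +
       inputs$area_impervious * (1 - ret$impervious) +
       inputs$area_wetland * (1 - ret$wetland))
}

#' Livestock nitrogen load for one decade
#'
#' Sum over animal types of count x excretion rate x (1 - loss
#' fraction); the dairy loss fraction reflects retention-pond capture.
#'
#' @param inputs one-row data.frame with livestock_dairy,
#'   livestock_other.
#' @param params an `nlm_params` (lists `livestock_excretion` and
#'   `livestock_loss` keyed by type).
#' @return kg N yr^-1.
#' @export
livestock_load <- function(inputs, params) {
  ex <- params$livestock_excretion
  lo <- params$livestock_loss
  inputs$livestock_dairy * ex$dairy * (1 - lo$dairy) +
    inputs$livestock_other * ex$other * (1 - lo$other)
}

#' Decadal watershed nitrogen budget
#'
#' Applies the four source models to every decade of the input history
#' and reports loads, the exact total, and source fractions.
#'
#' @param inputs decadal history (as from [gen_watershed_history()] or a
#'   CSV with the same columns).
#' @param params an `nlm_params`.
#' @return data.frame of class `nlm_budget`: decade, fertilizer,
#'   wastewater, atmospheric, livestock, total (kg N yr^-1) and
#'   frac_fertilizer .. frac_livestock.
#' @export
nlm_budget <- function(inputs, params = nlm_params()) {
  if (!inherits(params, "nlm_params")) params <- do.call(
    structure, c(list(params), class = "nlm_params"))
  neg <- vapply(c("population", "area_cultivated", "fertilizer_rate",
                  "livestock_dairy", "livestock_other"),
                function(cc) any(inputs[[cc]] < 0), FALSE)
  if (any(neg)) stop("NLM inputs must be non-negative", call. = FALSE)
  out <- data.frame(
    decade = inputs$decade,
    fertilizer = fertilizer_load(inputs, params),
    wastewater = wastewater_load(inputs, params),
    atmospheric = atmospheric_load(inputs, params),
    livestock = livestock_load(inputs, params))
  out$total <- out$fertilizer + out$wastewater + out$atmospheric +
    out$livestock
  for (src in c("fertilizer", "wastewater", "atmospheric", "livestock")) {
    out[[paste0("frac_", src)]] <- ifelse(out$total > 0,
                                          out[[src]] / out$total, 0)
  }
  structure(out, class = c("nlm_budget", "data.frame"))
}

#' Largest nitrogen source per decade
#'
#' @param budget an `nlm_budget`.
#' @return character vector, one source name per decade.
#' @export
dominant_source <- function(budget) {
  srcs <- c("fertilizer", "wastewater", "atmospheric", "livestock")
  srcs[apply(as.matrix(budget[, srcs]), 1, which.max)]
}
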