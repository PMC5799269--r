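#' Soil water constants of the experimental chernozem soil
#'
#' Volumetric water contents (cm^3 cm^-3) characterising the field soil:
#' saturation, field capacity and permanent wilting point. The saturation
#' value is the divisor used to convert volumetric soil water content (SWC)
#' into relative water saturation, theta_rel = SWC / sat_wc.
#'
#' @param sat_wc Saturation water content, cm^3 cm^-3.
#' @param field_capacity Field capacity, cm^3 cm^-3.
#' @param wilting_point Permanent wilting point, cm^3 cm^-3.
#'
#' @return An object of class \code{soil_water_constants}: a named list with
#'   elements \code{sat_wc}, \code{field_capacity}, \code{wilting_point}.
#' @examples
#' swc <- soil_water_constants()
#' swc$sat_wc    # 0.476: volumetric SWC at full saturation
#' @export
soil_water_constants <- function(sat_wc = 0.476,
                                 field_capacity = 0.305,
                                 wilting_point = 0.097) {
  stopifnot(is.numeric(sat_wc), is.numeric(field_capacity),
            is.numeric(wilting_point))
  if (!(0 < wilting_point && wilting_point < field_capacity &&
        field_capacity < sat_wc)) {
    stop("soil water constants must satisfy 0 < wilting_point < ",
         "field_capacity < sat_wc", call. = FALSE)
  }
  structure(list(sat_wc = sat_wc,
                 field_capacity = field_capacity,
                 wilting_point = wilting_point),
            class = "soil_water_constants")
}

#' Species-specific calibration constants
#'
#' The exponential calibration C_rel = a * exp(b * theta_rel) links the
#' relative root capacitance (C_rel, the ratio of measured root capacitance
#' C_R to the plant's own reading in water-saturated soil) to the relative
#' water saturation of the soil around the roots. Its inversion,
#' C_R* = C_R * k * exp(-b * theta_rel) with k = 1/a, converts a field
#' reading taken at any moisture level into the apparent saturation
#' capacitance C_R*, a moisture-independent indicator of root activity.
#'
#' Two presets are shipped per species. \code{"printed"} carries the
#' constants exactly as published for these crops grown in chernozem soil
#' (maize: a = 0.130, b = 2.028, k = 7.692; soybean: a = 0.244, b = 1.392,
#' k = 4.107); note the published soybean k was derived from an unrounded
#' intercept, so k * a is 1 only to ~2e-3 there. \code{"derived"} enforces
#' internal consistency, k = 1/a exactly.
#'
#' @param species \code{"maize"} or \code{"soybean"}.
#' @param source \code{"printed"} (published constants, default) or
#'   \code{"derived"} (k recomputed as 1/a).
#'
#' @return A \code{species_calibration} object; see
#'   \code{\link{new_species_calibration}}.
#' @examples
#' species_constants("maize")$k            # 7.692
#' species_constants("soybean")$k          # 4.107 (printed)
#' species_constants("soybean", "derived")$k  # 1/0.244 = 4.098...
#' @export
species_constants <- function(species = c("maize", "soybean"),
                              source = c("printed", "derived")) {
  species <- match.arg(species)
  source <- match.arg(source)
  con <- switch(species,
    maize   = list(a = 0.130, b = 2.028, k_printed = 7.692, r2 = 0.911),
    soybean = list(a = 0.244, b = 1.392, k_printed = 4.107, r2 = 0.902))
  k <- if (source == "printed") con$k_printed else 1 / con$a
  new_species_calibration(species = species, a = con$a, b = con$b, k = k,
                          r2 = con$r2, n_obs = 150L, n_plants = 15L,
                          source = source)
}

#' Reference soil capacitance power law
#'
#' Soil capacitance between two ground electrodes increases with relative
#' water saturation as C_S = coeff * theta_rel^expnt; at saturation it
#' reaches about 346 nF in this soil, at least an order of magnitude above
#' any root capacitance measured alongside it (the precondition for the
#' root tissue dominating the plant-soil capacitance reading).
#'
#' @return A \code{soil_capacitance_model} with the reference constants
#'   (coeff = 350.3 nF, expnt = 1.086, r2 = 0.934).
#' @export
reference_soil_model <- function() {
  new_soil_capacitance_model(coeff = 350.3, expnt = 1.086, r2 = 0.934,
                             n = 300L)
}
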