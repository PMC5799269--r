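# Domain containers and CSV/config I/O shared by every pipeline stage.
# Readings travel as plain data frames (one row per (plant, time) reading);
# fitted objects are light S3 lists.

#' Construct a species calibration object
#'
#' @param species "maize" or "soybean".
#' @param a Intercept of C_rel = a * exp(b * theta_rel), natural scale, > 0.
#' @param b Exponential slope, dimensionless, > 0 for these crops.
#' @param k Inversion constant; defaults to 1/a. Invariant: when derived,
#'   k * a == 1 to machine precision.
#' @param r2 Pooled ln-scale coefficient of determination.
#' @param n_obs,n_plants Observation and plant counts behind the fit.
#' @param source Provenance of k: "printed", "derived", or "fitted".
#' @return A \code{species_calibration} object.
#' @export
new_species_calibration <- function(species, a, b, k = 1 / a, r2 = NA_real_,
                                    n_obs = NA_integer_,
                                    n_plants = NA_integer_,
                                    source = "derived") {
  if (!is.numeric(a) || a <= 0) stop("'a' must be positive", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("'k' must be positive", call. = FALSE)
  structure(list(species = species, a = a, b = b, k = k, r2 = r2,
                 n_obs = as.integer(n_obs), n_plants = as.integer(n_plants),
                 source = source),
            class = "species_calibration")
}

#' @export
print.species_calibration <- function(x, ...) {
  cat(sprintf("Species calibration (%s, constants: %s)\n", x$species,
              x$source))
  cat(sprintf("  C_rel  = %.3f * exp(%.3f * theta_rel)   [R2 = %.3f]\n",
              x$a, x$b, x$r2))
  cat(sprintf("  C_R*   = C_R * %.3f * exp(-%.3f * theta_rel)\n", x$k, x$b))
  if (!is.na(x$n_plants))
    cat(sprintf("  fitted on %d plants, %d readings\n", x$n_plants, x$n_obs))
  invisible(x)
}

#' Construct a per-plant calibration result
#'
#' @param plant_id Plant identifier.
#' @param a_i,b_i Plant-level intercept and slope of the ln-linear fit of
#'   log(C_rel) on theta_rel (a_i on the natural scale).
#' @param r2_ln Ln-scale R-squared of the fit, in [0, 1].
#' @param r2_adj Small-sample adjusted R-squared.
#' @param c_r_sat Saturated-soil capacitance reading, nF.
#' @param n Number of readings used.
#' @return A \code{plant_calibration} object.
#' @export
new_plant_calibration <- function(plant_id, a_i, b_i, r2_ln,
                                  r2_adj = NA_real_, c_r_sat = NA_real_,
                                  n = NA_integer_) {
  if (a_i <= 0) stop("plant-level intercept a_i must be positive",
                     call. = FALSE)
  if (!is.na(r2_ln) && (r2_ln < -1e-12 || r2_ln > 1 + 1e-12))
    stop("r2_ln must lie in [0, 1]", call. = FALSE)
  structure(list(plant_id = plant_id, a_i = a_i, b_i = b_i,
                 r2_ln = min(max(r2_ln, 0), 1), r2_adj = r2_adj,
                 c_r_sat = c_r_sat, n = as.integer(n)),
            class = "plant_calibration")
}

#' Construct a pot wetting-up series for one plant
#'
#' One plant's calibration series: capacitance readings taken at a strictly
#' increasing sequence of relative water saturations, ending with the
#' water-saturated reading (theta_rel = 1) that defines the plant's own
#' normalizer C_R*(sat).
#'
#' @param plant_id Identifier shared by all readings of the plant.
#' @param species "maize" or "soybean".
#' @param theta_rel Strictly increasing vector in (0, 1], last element 1.
#' @param c_r Positive capacitance readings, nF, same length.
#' @param age_days Plant age at measurement, days (optional).
#' @param rdm Root dry mass at harvest, grams (optional).
#' @return A \code{pot_series} object. Its \code{c_r_sat} element is the
#'   reading at theta_rel = 1.
#' @export
new_pot_series <- function(plant_id, species, theta_rel, c_r,
                           age_days = NA_integer_, rdm = NA_real_) {
  if (length(theta_rel) != length(c_r))
    stop("theta_rel and c_r lengths differ", call. = FALSE)
  if (any(c_r <= 0)) stop("all c_r must be positive", call. = FALSE)
  if (any(theta_rel <= 0) || any(theta_rel > 1))
    stop("theta_rel must lie in (0, 1]", call. = FALSE)
  if (any(diff(theta_rel) <= 0))
    stop("theta_rel must be strictly increasing within a pot series ",
         "(wetting-up protocol)", call. = FALSE)
  structure(list(plant_id = plant_id, species = species,
                 theta_rel = as.numeric(theta_rel), c_r = as.numeric(c_r),
                 c_r_sat = if (theta_rel[length(theta_rel)] == 1)
                   c_r[length(c_r)] else NA_real_,
                 age_days = as.integer(age_days), rdm = rdm),
            class = "pot_series")
}

#' Construct a soil capacitance power-law model
#'
#' @param coeff Coefficient, nF (C_S at theta_rel = 1). Must be > 0.
#' @param expnt Dimensionless exponent. Must be > 0.
#' @param r2 Ln-scale R-squared of the fit.
#' @param n Number of (theta_rel, C_S) pairs.
#' @return A \code{soil_capacitance_model} object.
#' @export
new_soil_capacitance_model <- function(coeff, expnt, r2 = NA_real_,
                                       n = NA_integer_) {
  if (coeff <= 0 || expnt <= 0)
    stop("soil model requires positive coefficient and exponent",
         call. = FALSE)
  structure(list(coeff = coeff, expnt = expnt, r2 = r2, n = as.integer(n)),
            class = "soil_capacitance_model")
}

#' Evaluate a soil capacitance model
#'
#' @param model A \code{soil_capacitance_model}.
#' @param theta_rel Relative saturation values in (0, 1].
#' @return Predicted soil capacitance, nF.
#' @export
predict_soil_capacitance <- function(model, theta_rel) {
  stopifnot(inherits(model, "soil_capacitance_model"))
  model$coeff * theta_rel^model$expnt
}

# ---------------------------------------------------------------------------
# CSV ingest

.schema_cols <- list(
  pot = c("plant_id", "species", "theta_rel|swc_vol", "c_r_nf"),
  field = c("plant_id", "species", "das", "group", "treatment",
            "theta_rel|swc_vol", "c_r_nf"),
  harvest = c("plant_id", "das", "treatment", "sdm")
)

.check_columns <- function(df, schema) {
  needed <- .schema_cols[[schema]]
  for (spec in needed) {
    alts <- strsplit(spec, "|", fixed = TRUE)[[1]]
    if (!any(alts %in% names(df)))
      stop(sprintf("schema '%s' requires column '%s'", schema,
                   paste(alts, collapse = "' or '")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read capacitance readings or harvest records from CSV
#'
#' Reads one of the three tabular interchange formats and validates every
#' row against the domain invariants. Water content may be supplied either
#' directly as \code{theta_rel} (relative saturation in [0, 1]) or as
#' volumetric soil water content \code{swc_vol} (cm^3 cm^-3), which is
#' converted at ingest as theta_rel = swc_vol / sat_wc; conversion never
#' happens downstream. theta_rel values marginally above 1 (at most 1.02,
#' instrument noise at saturation) are clamped to 1 with a warning; larger
#' values are validation errors.
#'
#' @param path CSV file path.
#' @param schema One of \code{"pot"} (columns plant_id, species,
#'   theta_rel | swc_vol, c_r_nf, optionally age_days, rdm), \code{"field"}
#'   (plant_id, species, das, group, treatment, theta_rel | swc_vol, c_r_nf,
#'   optionally bbch) or \code{"harvest"} (plant_id, das, treatment, sdm,
#'   optionally grain_dm, m_pct).
#' @param swc SoilWaterConstants used for the volumetric conversion;
#'   defaults to \code{\link{soil_water_constants}()}.
#' @return A validated data frame with \code{theta_rel} populated (pot and
#'   field schemas).
#' @export
read_readings <- function(path, schema = c("pot", "field", "harvest"),
                          swc = soil_water_constants()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, schema)
  if (schema == "harvest") return(validate_harvest(df))
  if (!"theta_rel" %in% names(df)) {
    df$theta_rel <- df$swc_vol / swc$sat_wc
    df$swc_vol <- NULL
  }
  validate_readings(df, schema)
}

#' Validate a data frame of capacitance readings
#'
#' Enforces the reading invariants: c_r_nf > 0 and theta_rel in [0, 1]
#' (after the saturation clamp). Offending rows are reported by index.
#'
#' @param df Data frame with at least \code{theta_rel} and \code{c_r_nf}.
#' @param schema "pot" or "field" (controls which label columns must exist).
#' @return The validated (possibly clamped) data frame, invisibly unchanged
#'   otherwise.
#' @export
validate_readings <- function(df, schema = "pot") {
  bad <- which(!is.finite(df$c_r_nf) | df$c_r_nf <= 0)
  if (length(bad))
    stop("non-positive c_r_nf in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  over <- which(df$theta_rel > 1 & df$theta_rel <= 1.02)
  if (length(over)) {
    warning("theta_rel marginally above saturation clamped to 1 in row(s): ",
            paste(over, collapse = ", "), call. = FALSE)
    df$theta_rel[over] <- 1
  }
  bad <- which(!is.finite(df$theta_rel) | df$theta_rel < 0 |
                 df$theta_rel > 1)
  if (length(bad))
    stop("theta_rel outside [0, 1] in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (schema == "field" && !all(df$treatment %in% c("CON", "INO", "none")))
    stop("treatment must be one of CON, INO, none", call. = FALSE)
  df
}

#' Validate harvest records
#'
#' @param df Data frame with sdm (g, >= 0) and optional grain_dm, m_pct
#'   (AMF colonization intensity, percent in [0, 100]).
#' @return The validated data frame.
#' @export
validate_harvest <- function(df) {
  bad <- which(!is.finite(df$sdm) | df$sdm < 0)
  if (length(bad))
    stop("negative or missing sdm in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if ("m_pct" %in% names(df)) {
    bad <- which(!is.na(df$m_pct) & (df$m_pct < 0 | df$m_pct > 100))
    if (length(bad))
      stop("m_pct outside [0, 100] in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Split a pot readings table into per-plant wetting-up series
#'
#' @param df Validated pot-schema data frame.
#' @return A list of \code{pot_series}, one per plant, in first-appearance
#'   order; within each plant the readings keep file order (the wetting-up
#'   protocol guarantees increasing theta_rel, which is re-checked).
#' @export
split_pot_series <- function(df) {
  ids <- unique(df$plant_id)
  lapply(ids, function(id) {
    sub <- df[df$plant_id == id, , drop = FALSE]
    if (length(unique(sub$species)) != 1L)
      stop("plant ", id, " has inconsistent species labels", call. = FALSE)
    new_pot_series(
      plant_id = id, species = sub$species[1],
      theta_rel = sub$theta_rel, c_r = sub$c_r_nf,
      age_days = if ("age_days" %in% names(sub)) sub$age_days[1] else NA,
      rdm = if ("rdm" %in% names(sub)) sub$rdm[1] else NA_real_)
  })
}

#' Write a summary or readings table to CSV
#'
#' Round-trip stable: re-reading the file reproduces all typed fields.
#'
#' @param records Non-empty data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("refusing to write an empty summary", call. = FALSE)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Config I/O (YAML)

#' Read a simulation/pipeline configuration from YAML
#'
#' The file may carry any subset of \code{\link{sim_config}} fields plus an
#' optional \code{soil_water} block (sat_wc, field_capacity, wilting_point);
#' missing fields fall back to the species defaults.
#'
#' @param path YAML file.
#' @return A list with elements \code{config} (a \code{sim_config}) and
#'   \code{soil_water} (a \code{soil_water_constants}).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  swc <- if (!is.null(raw$soil_water))
    do.call(soil_water_constants, raw$soil_water)
  else soil_water_constants()
  raw$soil_water <- NULL
  cfg <- do.call(sim_config, raw)
  list(config = cfg, soil_water = swc)
}

#' Write a configuration to YAML
#'
#' @param config A \code{sim_config}.
#' @param path Output file.
#' @param soil_water Optional \code{soil_water_constants} to embed.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path, soil_water = NULL) {
  x <- unclass(config)
  x$field_days <- lapply(seq_len(nrow(config$field_days)), function(i)
    as.list(config$field_days[i, ]))
  if (!is.null(soil_water)) x$soil_water <- unclass(soil_water)
  yaml::write_yaml(x, path)
  invisible(path)
}
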