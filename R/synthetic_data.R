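# Seeded generators for pot-calibration series, field campaigns, soil
# capacitance surveys and destructive harvests. Measurement noise is
# multiplicative lognormal on capacitance (additive on the ln scale, the
# scale all fitting happens on); a lognormal plant-level random effect
# carries between-plant size variation.

#' Simulation configuration
#'
#' Full parameterisation of the synthetic generators. Defaults are the
#' study conditions of the reference experiments: 15 pot plants per species
#' on a 10-level wetting-up grid from near wilting point (theta_rel = 0.20)
#' to saturation; generating calibration constants equal to the species
#' presets; lognormal measurement noise sigma_ln = 0.10 on ln C_R; root dry
#' mass uniform over the harvested range (maize 0.37-11.10 g, soybean
#' 0.32-6.21 g); field campaigns of 48 plants/day (3 replicate groups of
#' 16) on the reference day grid with the empirical seasonal C_R* template;
#' a +5% multiplicative AMF uplift on inoculated plants within a mid-season
#' window (days 50-90 after sowing); and the reference soil power law with
#' noise sized to its published fit quality.
#'
#' @param species "maize" or "soybean".
#' @param seed Default random seed used by the generators when no seed is
#'   passed explicitly.
#' @param n_plants Pot plants per species.
#' @param theta_grid Strictly increasing wetting-up grid ending at 1.
#' @param gen_a,gen_b Generating calibration constants (defaults: species
#'   preset).
#' @param sigma_ln Lognormal measurement noise SD on ln C_R.
#' @param rdm_range Root dry mass range, g.
#' @param mass_slope,mass_intercept Linear RDM -> saturated-capacitance map
#'   (nF/g, nF).
#' @param mass_noise Lognormal SD of the mass relation.
#' @param age_range Pot plant ages, days (staggered plantings).
#' @param field_days Data frame (das, mean_theta, sd_theta, mean_cstar,
#'   bbch); default \code{\link{seasonal_cstar_template}} for the species.
#' @param n_per_day Field plants measured per day and treatment.
#' @param n_groups Replicate row-segments/plots per treatment.
#' @param sigma_plant Lognormal SD of the plant-level size effect in the
#'   field.
#' @param treatment_uplift Fractional C_R* uplift of INO plants.
#' @param uplift_window Days-after-sowing window (start, end) in which the
#'   uplift applies.
#' @param n_soil Soil survey size.
#' @param soil_coeff,soil_expnt,soil_sigma Soil power law and its lognormal
#'   noise SD (0.125 reproduces the published ln-scale fit quality).
#' @param sdm_final,sdm_cv Final-harvest shoot dry mass mean (g) and CV of
#'   the control treatment.
#' @param sdm_uplift Fractional SDM uplift of INO inside the uplift window
#'   (half of it applies after the window).
#' @param harvest_days,harvest_n Destructive sampling days and plants per
#'   plot (last entry is the final harvest).
#' @param grain_mean,grain_cv Final-harvest grain dry mass per plant.
#' @return A \code{sim_config} object (named list).
#' @export
sim_config <- function(species = c("maize", "soybean"),
                       seed = 1L,
                       n_plants = 15L,
                       theta_grid = seq(0.20, 1, length.out = 10),
                       gen_a = NULL, gen_b = NULL,
                       sigma_ln = 0.10,
                       rdm_range = NULL,
                       mass_slope = NULL, mass_intercept = 0.5,
                       mass_noise = 0.19,
                       age_range = c(13L, 62L),
                       field_days = NULL,
                       n_per_day = 48L, n_groups = 3L,
                       sigma_plant = 0.10,
                       treatment_uplift = 0.05,
                       uplift_window = c(50, 90),
                       n_soil = 300L,
                       soil_coeff = 350.3, soil_expnt = 1.086,
                       soil_sigma = 0.125,
                       sdm_final = 51, sdm_cv = 0.30,
                       sdm_uplift = 0.15,
                       harvest_days = c(48L, 71L, 99L, 135L, 164L),
                       harvest_n = c(6L, 6L, 6L, 6L, 10L),
                       grain_mean = 19.5, grain_cv = 0.33) {
  species <- match.arg(species)
  preset <- species_constants(species, source = "printed")
  if (is.null(gen_a)) gen_a <- preset$a
  if (is.null(gen_b)) gen_b <- preset$b
  if (is.null(rdm_range))
    rdm_range <- if (species == "maize") c(0.37, 11.10) else c(0.32, 6.21)
  if (is.null(mass_slope))
    mass_slope <- if (species == "maize") 3.75 else 1.96
  if (is.null(field_days)) field_days <- seasonal_cstar_template(species)
  if (is.list(field_days) && !is.data.frame(field_days))
    field_days <- do.call(rbind, lapply(field_days, as.data.frame))
  if (any(diff(theta_grid) <= 0) || theta_grid[length(theta_grid)] != 1)
    stop("theta_grid must be strictly increasing and end at 1",
         call. = FALSE)
  if (sigma_ln < 0 || sigma_plant < 0 || soil_sigma < 0 || mass_noise < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  structure(list(
    species = species, seed = as.integer(seed), n_plants = as.integer(n_plants),
    theta_grid = theta_grid, gen_a = gen_a, gen_b = gen_b,
    sigma_ln = sigma_ln, rdm_range = rdm_range, mass_slope = mass_slope,
    mass_intercept = mass_intercept, mass_noise = mass_noise,
    age_range = as.integer(age_range), field_days = field_days,
    n_per_day = as.integer(n_per_day), n_groups = as.integer(n_groups),
    sigma_plant = sigma_plant, treatment_uplift = treatment_uplift,
    uplift_window = uplift_window, n_soil = as.integer(n_soil),
    soil_coeff = soil_coeff, soil_expnt = soil_expnt,
    soil_sigma = soil_sigma, sdm_final = sdm_final, sdm_cv = sdm_cv,
    sdm_uplift = sdm_uplift, harvest_days = as.integer(harvest_days),
    harvest_n = as.integer(harvest_n), grain_mean = grain_mean,
    grain_cv = grain_cv), class = "sim_config")
}

.set_seed <- function(config, seed) {
  s <- if (is.null(seed)) config$seed else seed
  if (!is.null(s)) set.seed(as.integer(s))
  invisible(s)
}

#' Simulate pot wetting-up calibration series
#'
#' Emulates the pot protocol: each plant gets a root dry mass drawn
#' uniformly from the harvested range, a saturated capacitance from the
#' linear mass relation (with lognormal scatter), and one reading per
#' theta_grid level following c_r = c_star * gen_a * exp(gen_b * theta)
#' times lognormal measurement noise. The saturated (theta = 1) reading is
#' noisy too, and — exactly as in the real protocol — that noisy reading
#' itself becomes the plant's normalizer, so each plant's C_rel series
#' passes through (1, 1) by construction.
#'
#' @param config A \code{sim_config}.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return List of \code{pot_series} of length \code{config$n_plants},
#'   with \code{rdm} and staggered \code{age_days} filled in.
#' @export
simulate_pot <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed(config, seed)
  n <- config$n_plants
  ages <- as.integer(round(seq(config$age_range[1], config$age_range[2],
                               length.out = n)))
  prefix <- if (config$species == "maize") "M" else "S"
  lapply(seq_len(n), function(i) {
    rdm <- stats::runif(1, config$rdm_range[1], config$rdm_range[2])
    c_star <- (config$mass_intercept + config$mass_slope * rdm) *
      exp(stats::rnorm(1, 0, config$mass_noise))
    c_r <- c_star * config$gen_a * exp(config$gen_b * config$theta_grid) *
      exp(stats::rnorm(length(config$theta_grid), 0, config$sigma_ln))
    new_pot_series(plant_id = sprintf("%s%02d", prefix, i),
                   species = config$species,
                   theta_rel = config$theta_grid, c_r = c_r,
                   age_days = ages[i], rdm = rdm)
  })
}

# Truncated-normal draw on (lo, hi] by rejection.
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a field campaign
#'
#' Emulates the field protocol: on each measurement day, \code{n_per_day}
#' plants per treatment (split over \code{n_groups} replicate
#' row-segments/plots) receive a soil moisture draw from a truncated normal
#' around the day's mean, a plant size C_R* drawn lognormally around the
#' seasonal template value, and a measured capacitance
#' c_r = c_star * gen_a * exp(gen_b * theta) times measurement noise.
#' Inoculated (INO) plants get their c_star multiplied by
#' (1 + treatment_uplift) on days inside the uplift window. For maize-style
#' campaigns (template treatment "none") a single untreated cohort is
#' generated; for soybean both CON and INO cohorts.
#'
#' @param config A \code{sim_config}.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return A list with \code{readings} (field-schema data frame with
#'   bbch) and \code{truth} (per-plant generating c_star, for recovery
#'   tests).
#' @export
simulate_field <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$field_days) == 0L)
    stop("field_days is empty", call. = FALSE)
  .set_seed(config, seed)
  treatments <- if (config$species == "soybean") c("CON", "INO") else "none"
  n <- config$n_per_day
  groups <- rep(paste0("G", seq_len(config$n_groups)),
                length.out = n)
  rows <- list(); truths <- list(); idx <- 0L
  for (d in seq_len(nrow(config$field_days))) {
    day <- config$field_days[d, ]
    for (tr in treatments) {
      idx <- idx + 1L
      theta <- .rtruncnorm(n, day$mean_theta, day$sd_theta)
      c_star <- day$mean_cstar * exp(stats::rnorm(n, 0, config$sigma_plant))
      if (tr == "INO" && day$das >= config$uplift_window[1] &&
          day$das <= config$uplift_window[2])
        c_star <- c_star * (1 + config$treatment_uplift)
      c_r <- c_star * config$gen_a * exp(config$gen_b * theta) *
        exp(stats::rnorm(n, 0, config$sigma_ln))
      pid <- sprintf("%s_d%03d_%s_p%02d", config$species, day$das, tr,
                     seq_len(n))
      rows[[idx]] <- data.frame(
        plant_id = pid, species = config$species, das = day$das,
        group = groups, treatment = tr, theta_rel = theta, c_r_nf = c_r,
        bbch = if ("bbch" %in% names(day)) day$bbch else NA_integer_)
      truths[[idx]] <- data.frame(plant_id = pid, das = day$das,
                                  treatment = tr, c_star_true = c_star)
    }
  }
  list(readings = do.call(rbind, rows), truth = do.call(rbind, truths))
}

#' Simulate a soil capacitance survey
#'
#' (theta_rel, C_S) pairs with theta uniform on (0.2, 1] and
#' C_S = soil_coeff * theta^soil_expnt times lognormal noise.
#'
#' @param config A \code{sim_config}.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return Data frame with columns \code{theta_rel}, \code{c_s_nf}.
#' @export
simulate_soil <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed(config, seed)
  theta <- stats::runif(config$n_soil, 0.2, 1)
  c_s <- config$soil_coeff * theta^config$soil_expnt *
    exp(stats::rnorm(config$n_soil, 0, config$soil_sigma))
  data.frame(theta_rel = theta, c_s_nf = c_s)
}

# Mean SDM growth curve: logistic in days after sowing, scaled so the
# control reaches sdm_final at the final harvest day.
.sdm_curve <- function(das, config) {
  t_mid <- 95; tau <- 18
  config$sdm_final / (1 + exp(-(das - t_mid) / tau))
}

# Mean AMF colonization intensity (%): moderate (~18-25%) before pod
# filling, rising steeply to ~80% by ripening.
.m_pct_curve <- function(das) 18 + 62 / (1 + exp(-(das - 120) / 10))

#' Simulate destructive harvests
#'
#' Shoot dry mass grows along a logistic curve (control reaching
#' \code{sdm_final} at the final harvest) with mean-one lognormal scatter of
#' CV \code{sdm_cv}; INO plants get (1 + sdm_uplift) inside the uplift
#' window and (1 + sdm_uplift/2) after it. AMF colonization intensity (M%)
#' follows a logistic rise from ~18% to ~80% with additive noise clamped to
#' [0, 100]; INO runs 5 points higher before pod filling. Grain dry mass is
#' drawn at the final harvest only.
#'
#' @param config A \code{sim_config}.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return Harvest-schema data frame: \code{plant_id}, \code{das},
#'   \code{treatment}, \code{plot}, \code{sdm}, \code{grain_dm},
#'   \code{m_pct}.
#' @export
simulate_harvest <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed(config, seed)
  sig <- sqrt(log(1 + config$sdm_cv^2))
  rows <- list(); idx <- 0L
  final_das <- config$harvest_days[length(config$harvest_days)]
  for (h in seq_along(config$harvest_days)) {
    das <- config$harvest_days[h]
    n_plot <- config$harvest_n[h]
    for (tr in c("CON", "INO")) {
      up <- if (tr == "INO") {
        if (das >= config$uplift_window[1] && das <= config$uplift_window[2])
          1 + config$sdm_uplift
        else if (das > config$uplift_window[2]) 1 + config$sdm_uplift / 2
        else 1
      } else 1
      for (plot in seq_len(config$n_groups)) {
        idx <- idx + 1L
        mu <- .sdm_curve(das, config) * up
        sdm <- mu * exp(stats::rnorm(n_plot, -sig^2 / 2, sig))
        m_mu <- .m_pct_curve(das) + if (tr == "INO" && das <= 99) 5 else 0
        m_pct <- pmin(100, pmax(0, stats::rnorm(n_plot, m_mu, 6)))
        grain <- if (das == final_das) {
          gsig <- sqrt(log(1 + config$grain_cv^2))
          config$grain_mean * exp(stats::rnorm(n_plot, -gsig^2 / 2, gsig))
        } else rep(NA_real_, n_plot)
        rows[[idx]] <- data.frame(
          plant_id = sprintf("h_d%03d_%s_P%d_%02d", das, tr, plot,
                             seq_len(n_plot)),
          das = das, treatment = tr, plot = paste0("P", plot),
          sdm = sdm, grain_dm = grain, m_pct = m_pct)
      }
    }
  }
  do.call(rbind, rows)
}
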