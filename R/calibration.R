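# Fit statistics computed directly from the lm object (avoids
# summary.lm's perfect-fit warning on noise-free calibration data).
.lm_stats <- function(fit) {
  y <- fit$model[[1]]
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  n <- length(y)
  df_res <- fit$df.residual
  r2_adj <- if (!is.na(r2) && df_res > 0)
    1 - (1 - r2) * (n - 1) / df_res else NA_real_
  s2 <- sse / df_res
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(s2 * diag(xtx_inv))
  tval <- stats::coef(fit) / se
  p <- 2 * stats::pt(-abs(tval), df_res)
  list(r2 = r2, r2_adj = r2_adj, p = p)
}

# Calibration stage: per-plant and pooled species C_rel-theta_rel fits,
# RDM-C_R mass calibrations, the soil capacitance power law, and the
# age/species fixed-effect screen. All capacitance fitting is done on the
# natural-log scale (the exponential model is exactly ln-linear); no
# nonlinear least squares anywhere.

#' Relative capacitance of a pot wetting-up series
#'
#' Divides every reading of one plant by that plant's own water-saturated
#' reading, giving the dimensionless relative capacitance
#' C_rel = C_R / C_R(sat). By construction the saturated point maps to
#' exactly (theta_rel = 1, c_rel = 1), which removes plant size from the
#' series — the property that lets plants of very different root mass be
#' pooled into one species calibration.
#'
#' @param series A \code{pot_series} whose last reading is at
#'   theta_rel = 1.
#' @return A data frame with columns \code{theta_rel}, \code{c_rel}.
#' @export
compute_c_rel <- function(series) {
  stopifnot(inherits(series, "pot_series"))
  if (is.na(series$c_r_sat))
    stop("series has no saturated reading (theta_rel = 1): ",
         "relative capacitance undefined", call. = FALSE)
  data.frame(theta_rel = series$theta_rel,
             c_rel = series$c_r / series$c_r_sat)
}

#' Fit one plant's exponential calibration
#'
#' Ordinary least squares of log(C_rel) on theta_rel — the ln-linearisation
#' of C_rel = a * exp(b * theta_rel). Returns the natural-scale intercept
#' a_i = exp(intercept), the slope b_i, and both plain and adjusted
#' ln-scale R-squared.
#'
#' @param series A \code{pot_series} with at least 3 distinct theta_rel
#'   levels and a saturated reading.
#' @return A \code{plant_calibration}.
#' @export
fit_plant <- function(series) {
  cr <- compute_c_rel(series)
  if (length(unique(cr$theta_rel)) < 3L)
    stop("need >= 3 distinct theta_rel values to fit a plant calibration",
         call. = FALSE)
  fit <- stats::lm(log(c_rel) ~ theta_rel, data = cr)
  st <- .lm_stats(fit)
  co <- stats::coef(fit)
  new_plant_calibration(
    plant_id = series$plant_id,
    a_i = exp(unname(co[1])), b_i = unname(co[2]),
    r2_ln = st$r2, r2_adj = st$r2_adj,
    c_r_sat = series$c_r_sat, n = nrow(cr))
}

# Per-plant ln-scale fit with coefficient covariance, for the two-stage
# pooling route.
.plant_fit_full <- function(series) {
  cr <- compute_c_rel(series)
  fit <- stats::lm(log(c_rel) ~ theta_rel, data = cr)
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  list(coef = stats::coef(fit), vcov = s2 * chol2inv(qr.R(fit$qr)),
       data = cbind(cr, plant_id = series$plant_id))
}

#' Fit the pooled species calibration
#'
#' Pools the per-plant ln-scale fits of log(C_rel) on theta_rel into one
#' species-level (a, b). Two routes are provided:
#' \describe{
#'   \item{\code{"two_stage"} (default)}{per-plant OLS followed by a
#'     precision-weighted (inverse-variance) mean of the coefficient
#'     vectors — the classical two-stage estimate of a random-intercept
#'     model. After C_rel normalisation the between-plant intercept
#'     variance is small by construction, so this is numerically very close
#'     to the full mixed model while remaining exactly testable.}
#'   \item{\code{"reml"}}{a linear mixed-effects model
#'     (\code{nlme::lme}) of log(C_rel) on theta_rel with a per-plant
#'     random intercept, fitted by REML.}
#' }
#' The pooled R-squared is computed on the ln scale from the fixed-effect
#' prediction over all readings. Both plain and adjusted versions are
#' returned (fields \code{r2}, \code{r2_adj}).
#'
#' @param plants List of \code{pot_series}, all of one species, length >= 2
#'   (a single series may be passed and is fitted directly).
#' @param method "two_stage" or "reml".
#' @return A \code{species_calibration} with \code{source = "fitted"} and
#'   k = 1/a at full precision.
#' @export
fit_species <- function(plants, method = c("two_stage", "reml")) {
  method <- match.arg(method)
  if (inherits(plants, "pot_series")) plants <- list(plants)
  sp <- unique(vapply(plants, `[[`, "", "species"))
  if (length(sp) != 1L)
    stop("fit_species requires a single species; got: ",
         paste(sp, collapse = ", "), call. = FALSE)

  fits <- lapply(plants, .plant_fit_full)
  all_data <- do.call(rbind, lapply(fits, `[[`, "data"))

  if (method == "two_stage" || length(plants) == 1L) {
    coefs <- t(vapply(fits, `[[`, numeric(2), "coef"))
    w <- t(vapply(fits, function(f) 1 / diag(f$vcov), numeric(2)))
    # inverse-variance weights per coefficient; equal designs => plain
    # mean. Noise-free plants have zero coefficient variance: fall back to
    # equal weights (every plant is then exact anyway).
    if (!all(is.finite(w))) w[] <- 1
    w <- sweep(w, 2, colSums(w), "/")
    beta <- colSums(coefs * w)
  } else {
    lme_fit <- nlme::lme(log(c_rel) ~ theta_rel, random = ~ 1 | plant_id,
                         data = all_data, method = "REML")
    beta <- nlme::fixed.effects(lme_fit)
  }

  pred <- beta[1] + beta[2] * all_data$theta_rel
  resid <- log(all_data$c_rel) - pred
  sst <- sum((log(all_data$c_rel) - mean(log(all_data$c_rel)))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  n <- nrow(all_data)
  r2_adj <- if (!is.na(r2) && n > 2) 1 - (1 - r2) * (n - 1) / (n - 2)
            else NA_real_

  out <- new_species_calibration(
    species = sp, a = exp(unname(beta[1])), b = unname(beta[2]),
    r2 = r2, n_obs = n, n_plants = length(plants), source = "fitted")
  out$r2_adj <- r2_adj
  out
}

#' Screen for age and species effects on the calibration
#'
#' Mixed-model screen for whether the C_rel-theta_rel relationship depends
#' on plant age or species: log(C_rel) is regressed on
#' theta_rel * age_days * species with a per-plant random intercept
#' (\code{nlme::lme}, ML). Two views are returned:
#' \describe{
#'   \item{\code{terms}}{the per-term marginal (Type III style) F table
#'     over all fixed terms of the full model;}
#'   \item{\code{joint}}{nested-model likelihood-ratio tests of the full
#'     model against reduced models dropping, in turn, every term involving
#'     plant age and every term involving species — one joint test per
#'     factor, which is the decision-relevant quantity (four individual age
#'     terms each at alpha would inflate the family-wise rate).}
#' }
#' Age-independence is what licenses one species-wide calibration across
#' phenological stages; a significant species effect (in practice the
#' theta_rel x species term) is what forces separate per-species constants.
#'
#' @param maize_plants,soybean_plants Lists of \code{pot_series}, one per
#'   species, with recorded \code{age_days}.
#' @param alpha Significance threshold (default 0.05).
#' @return A list of class \code{effect_screen} with data frames
#'   \code{terms} (term, num_df, den_df, f_value, p_value, significant)
#'   and \code{joint} (factor, df, lr_stat, p_value, significant).
#' @export
test_age_species_effects <- function(maize_plants, soybean_plants,
                                     alpha = 0.05) {
  sp1 <- unique(vapply(maize_plants, `[[`, "", "species"))
  sp2 <- unique(vapply(soybean_plants, `[[`, "", "species"))
  if (length(sp1) != 1L || length(sp2) != 1L || sp1 == sp2)
    stop("need two plant lists of two distinct species", call. = FALSE)

  stack_one <- function(plants) {
    do.call(rbind, lapply(plants, function(s) {
      cr <- compute_c_rel(s)
      cbind(cr, plant_id = s$plant_id, species = s$species,
            age_days = s$age_days)
    }))
  }
  df <- rbind(stack_one(maize_plants), stack_one(soybean_plants))
  if (anyNA(df$age_days))
    stop("all plants need a recorded age_days", call. = FALSE)

  form <- log(c_rel) ~ theta_rel * age_days * species
  drop_age <- any(vapply(split(df$age_days, df$species),
                         function(a) length(unique(a)) < 2L, TRUE))
  if (drop_age) {
    warning("constant plant age within a species: age terms dropped",
            call. = FALSE)
    form <- log(c_rel) ~ theta_rel * species
  }
  fit <- nlme::lme(form, random = ~ 1 | plant_id, data = df, method = "ML")
  an <- stats::anova(fit, type = "marginal")
  terms <- data.frame(term = rownames(an), num_df = an$numDF,
                      den_df = an$denDF, f_value = an$`F-value`,
                      p_value = an$`p-value`, row.names = NULL)
  terms$significant <- terms$p_value < alpha

  lrt <- function(reduced_form) {
    red <- nlme::lme(reduced_form, random = ~ 1 | plant_id, data = df,
                     method = "ML")
    cmp <- stats::anova(red, fit)
    c(df = cmp$df[2] - cmp$df[1], lr_stat = cmp$L.Ratio[2],
      p_value = cmp$`p-value`[2])
  }
  joint_list <- list(
    species = lrt(if (drop_age) log(c_rel) ~ theta_rel
                  else log(c_rel) ~ theta_rel * age_days))
  if (!drop_age)
    joint_list$age <- lrt(log(c_rel) ~ theta_rel * species)
  joint <- data.frame(factor = names(joint_list),
                      do.call(rbind, joint_list), row.names = NULL)
  joint$significant <- joint$p_value < alpha

  structure(list(terms = terms, joint = joint, alpha = alpha),
            class = "effect_screen")
}

#' @export
print.effect_screen <- function(x, ...) {
  cat("Fixed-effect screen on log(C_rel) ~ theta_rel * age * species\n")
  cat("Per-term marginal F tests:\n")
  print(x$terms, digits = 4)
  cat("Joint (nested-model) likelihood-ratio tests:\n")
  print(x$joint, digits = 4)
  invisible(x)
}

#' Linear root-mass calibration
#'
#' OLS of root capacitance on root dry mass, the classical calibration that
#' lets C_R (at a fixed moisture condition: wilting point or saturation)
#' predict root dry mass.
#'
#' @param c_r Capacitance readings, nF.
#' @param rdm Root dry masses, g; same length, >= 3, non-constant.
#' @param condition "wilting_point" or "saturated" (label only).
#' @return A \code{mass_calibration} object with \code{slope} (nF/g),
#'   \code{intercept} (nF), \code{r2}, \code{n}, \code{condition}.
#' @export
fit_mass_calibration <- function(c_r, rdm,
                                 condition = c("saturated",
                                               "wilting_point")) {
  condition <- match.arg(condition)
  if (length(c_r) != length(rdm))
    stop("c_r and rdm lengths differ", call. = FALSE)
  if (length(rdm) < 3L)
    stop("need >= 3 plants for a mass calibration", call. = FALSE)
  if (stats::var(rdm) == 0)
    stop("rdm has zero variance: slope undefined", call. = FALSE)
  fit <- stats::lm(c_r ~ rdm)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = .lm_stats(fit)$r2,
                 n = length(rdm), condition = condition),
            class = "mass_calibration")
}

#' Fit the soil capacitance power law
#'
#' Fits C_S = coeff * theta_rel^expnt by OLS of log(C_S) on log(theta_rel)
#' (the exact linearisation of the power law).
#'
#' @param theta_rel Relative saturations, all > 0.
#' @param c_s Soil capacitance readings, nF, all > 0.
#' @return A \code{soil_capacitance_model}.
#' @export
fit_soil_model <- function(theta_rel, c_s) {
  if (length(theta_rel) != length(c_s))
    stop("theta_rel and c_s lengths differ", call. = FALSE)
  if (any(theta_rel <= 0) || any(c_s <= 0))
    stop("power-law fit requires positive theta_rel and c_s", call. = FALSE)
  fit <- stats::lm(log(c_s) ~ log(theta_rel))
  new_soil_capacitance_model(
    coeff = exp(unname(stats::coef(fit)[1])),
    expnt = unname(stats::coef(fit)[2]),
    r2 = .lm_stats(fit)$r2, n = length(c_s))
}
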