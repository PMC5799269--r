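# Day-level reference statistics of the two field campaigns (chernozem site,
# 2015 season). These published summary tables are the only field data that
# exist for this system; they serve as worked-example inputs and as the
# seasonal template the synthetic field generator is calibrated to.

#' Day-level reference statistics of the field campaigns
#'
#' Per measurement day: days after sowing (das), mean and SD of relative
#' water saturation around the roots (theta_rel, n = 48 plants), mean and SD
#' of measured root capacitance (c_r, nF), the BBCH phenology code, and the
#' treatment label ("none" for the maize campaign; "CON"/"INO" for the
#' control and AMF-inoculated soybean plots).
#'
#' @param species \code{"maize"} or \code{"soybean"}.
#' @return A data frame with columns \code{das}, \code{treatment},
#'   \code{mean_theta}, \code{sd_theta}, \code{mean_cr}, \code{sd_cr},
#'   \code{bbch}, \code{n}.
#' @examples
#' head(field_reference_days("maize"))
#' @export
field_reference_days <- function(species = c("maize", "soybean")) {
  species <- match.arg(species)
  if (species == "maize") {
    df <- data.frame(
      das = c(36L, 50L, 64L, 78L, 92L, 106L, 123L, 134L, 147L, 161L),
      treatment = "none",
      mean_theta = c(0.516, 0.488, 0.236, 0.537, 0.338, 0.214, 0.547,
                     0.237, 0.266, 0.521),
      sd_theta = c(0.054, 0.045, 0.023, 0.067, 0.033, 0.018, 0.052,
                   0.023, 0.023, 0.041),
      mean_cr = c(4.71, 15.09, 13.74, 34.46, 25.02, 16.24, 19.28,
                  7.06, 5.24, 2.35),
      sd_cr = c(0.86, 2.78, 2.60, 3.84, 3.63, 1.73, 2.76, 0.78, 1.37, 0.41),
      bbch = c(14L, 17L, 19L, 63L, 67L, 73L, 83L, 87L, 89L, 97L),
      n = 48L)
    return(df)
  }
  das <- c(39L, 54L, 69L, 83L, 97L, 113L, 125L, 139L, 150L, 162L)
  bbch <- c(12L, 14L, 60L, 65L, 73L, 75L, 77L, 81L, 85L, 89L)
  con <- data.frame(
    das = das, treatment = "CON",
    mean_theta = c(0.413, 0.245, 0.401, 0.354, 0.319, 0.632, 0.278,
                   0.326, 0.655, 0.743),
    sd_theta = c(0.033, 0.018, 0.036, 0.038, 0.025, 0.037, 0.021,
                 0.028, 0.038, 0.031),
    mean_cr = c(2.00, 2.47, 5.21, 8.77, 8.25, 12.36, 6.93, 4.81,
                3.55, 2.14),
    sd_cr = c(0.12, 0.26, 0.46, 0.69, 0.64, 1.05, 0.53, 0.58, 0.30, 0.26),
    bbch = bbch, n = 48L)
  ino <- data.frame(
    das = das, treatment = "INO",
    mean_theta = c(0.415, 0.242, 0.400, 0.356, 0.325, 0.641, 0.276,
                   0.330, 0.663, 0.746),
    sd_theta = c(0.031, 0.019, 0.032, 0.033, 0.022, 0.034, 0.024,
                 0.024, 0.031, 0.029),
    mean_cr = c(2.01, 2.58, 5.35, 8.98, 8.41, 12.70, 6.99, 4.86,
                3.61, 2.19),
    sd_cr = c(0.13, 0.27, 0.42, 0.70, 0.63, 1.28, 0.55, 0.56, 0.29, 0.27),
    bbch = bbch, n = 48L)
  rbind(con, ino)
}

#' Seasonal apparent-capacitance template for the synthetic field generator
#'
#' For each measurement day of the reference campaign, the apparent
#' saturation capacitance C_R* obtained by applying the species inversion
#' (printed constants) to the day's mean C_R and mean theta_rel. This
#' empirical lookup table — unimodal with a peak at flowering — is the
#' default ground-truth profile \code{\link{simulate_field}} draws plant
#' sizes around; no parametric seasonal curve is imposed.
#'
#' @param species \code{"maize"} or \code{"soybean"}.
#' @param treatment Treatment rows to use for soybean ("CON" default).
#' @return A data frame with columns \code{das}, \code{mean_theta},
#'   \code{sd_theta}, \code{mean_cstar}, \code{bbch}.
#' @export
seasonal_cstar_template <- function(species = c("maize", "soybean"),
                                    treatment = "CON") {
  species <- match.arg(species)
  ref <- field_reference_days(species)
  if (species == "soybean") ref <- ref[ref$treatment == treatment, ]
  cal <- species_constants(species, source = "printed")
  ref$mean_cstar <- apparent_capacitance(ref$mean_cr, ref$mean_theta, cal)
  ref[, c("das", "mean_theta", "sd_theta", "mean_cstar", "bbch")]
}
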