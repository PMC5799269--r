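# Shared fixture builders. Everything is generated in code; no files ship.

# Noise-free pot series following c_r = scale * a * exp(b * theta) on the
# default 10-level wetting-up grid.
exact_series <- function(a, b, scale = 10, species = "maize",
                         plant_id = "P1", age_days = 30,
                         theta = seq(0.2, 1, length.out = 10)) {
  new_pot_series(plant_id = plant_id, species = species,
                 theta_rel = theta, c_r = scale * a * exp(b * theta),
                 age_days = age_days)
}

# Brute-force oracle for the ln-scale OLS: grid search minimizing the
# ln-scale SSE over (intercept, slope). Independent of lm().
grid_search_lnfit <- function(theta, c_rel, int_range, slope_range,
                              step = 5e-4) {
  ints <- seq(int_range[1], int_range[2], by = step)
  slopes <- seq(slope_range[1], slope_range[2], by = step)
  y <- log(c_rel)
  best <- c(NA, NA); best_sse <- Inf
  for (b in slopes) {
    r <- y - b * theta
    # optimal intercept for fixed slope is mean(r); restrict to grid
    i0 <- ints[which.min(abs(ints - mean(r)))]
    sse <- sum((r - i0)^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(i0, b) }
  }
  best
}

# Write a data frame to a temp CSV and return the path.
tmp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}

# A tiny well-formed pot readings table (one plant, 10 readings).
pot_df <- function(theta = seq(0.2, 1, length.out = 10),
                   c_r = 10 * 0.13 * exp(2.028 * theta)) {
  data.frame(plant_id = "M01", species = "maize", age_days = 30,
             theta_rel = theta, c_r_nf = c_r, rdm = 2.5)
}
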