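test_that("relative capacitance normalises by the saturated reading", {
  theta <- c(0.25, 0.5, 1)
  s <- new_pot_series("P", "maize", theta, c(10.5, 21.05, 42.1))
  cr <- compute_c_rel(s)
  expect_equal(cr$c_rel[3], 1)            # saturated reading maps to 1
  expect_equal(cr$c_rel[2], 0.5)          # halving
  expect_error(compute_c_rel(new_pot_series("P", "maize", c(0.2, 0.5),
                                            c(1, 2))),
               "no saturated reading")
})

test_that("normalisation rescales the curve by its saturation value", {
  # c_r built exactly as 10 * 0.13 * exp(2.028 theta): c_rel differs from
  # 0.13 * exp(2.028 theta) only by the normalizer 0.13 * e^2.028 = 0.988
  s <- exact_series(0.13, 2.028)
  cr <- compute_c_rel(s)
  expect_equal(cr$c_rel, 0.13 * exp(2.028 * cr$theta_rel) /
                 (0.13 * exp(2.028)), tolerance = 1e-12)
  expect_true(all(abs(cr$c_rel / (0.13 * exp(2.028 * cr$theta_rel)) - 1)
                  < 0.013))
})

test_that("per-plant fit inverts the generator exactly without noise", {
  # self-normalisation forces c_rel(1) = 1, so only generators with
  # a * e^b = 1 survive the chain unchanged: use a = exp(-b)
  a <- exp(-1.5)
  s <- exact_series(a, 1.5, scale = 6)
  fit <- fit_plant(s)
  expect_equal(fit$a_i, a, tolerance = 1e-10)
  expect_equal(fit$b_i, 1.5, tolerance = 1e-10)
  expect_equal(fit$r2_ln, 1, tolerance = 1e-10)
})

test_that("degenerate series are rejected", {
  expect_error(fit_plant(new_pot_series("P", "maize", c(0.5, 1),
                                        c(2, 4))),
               ">= 3 distinct")
})

test_that("ln-scale OLS matches a brute-force SSE grid search", {
  # 4-point series with noise baked into the values
  theta <- c(0.3, 0.55, 0.8, 1)
  c_rel <- c(0.21, 0.33, 0.62, 1)
  s <- new_pot_series("P", "maize", theta, c_rel * 7.3)
  fit <- fit_plant(s)
  oracle <- grid_search_lnfit(theta, c_rel,
                              int_range = c(-2.5, -1), slope_range = c(1, 3))
  expect_equal(log(fit$a_i), oracle[1], tolerance = 1e-3)
  expect_equal(fit$b_i, oracle[2], tolerance = 1e-3)
})

test_that("pooling degenerates correctly", {
  s <- exact_series(0.13, 2.028, scale = 4)
  single <- fit_plant(s)
  pooled <- fit_species(list(s, s, s))
  expect_equal(pooled$a, single$a_i, tolerance = 1e-12)
  expect_equal(pooled$b, single$b_i, tolerance = 1e-12)

  # noise-free identical plants: perfect pooled fit, k * a == 1
  plants <- lapply(1:15, function(i)
    exact_series(0.13, 2.028, scale = i, plant_id = paste0("M", i)))
  sp <- fit_species(plants)
  expect_equal(sp$r2, 1, tolerance = 1e-12)
  expect_equal(sp$k * sp$a, 1, tolerance = 1e-12)
  expect_equal(sp$n_obs, 150L)
  expect_equal(sp$n_plants, 15L)
})

test_that("pooled fit is invariant to plant size rescaling", {
  cfg <- sim_config("maize", seed = 11)
  plants <- simulate_pot(cfg)
  scaled <- lapply(plants, function(s) {
    s$c_r <- s$c_r * 37.5
    s$c_r_sat <- s$c_r_sat * 37.5
    s
  })
  f1 <- fit_species(plants)
  f2 <- fit_species(scaled)
  expect_equal(f1$a, f2$a, tolerance = 1e-12)
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
})

test_that("pooled coefficients stay inside the per-plant ranges", {
  plants <- simulate_pot(sim_config("soybean", seed = 5))
  per <- t(sapply(plants, function(s) {
    f <- fit_plant(s); c(f$a_i, f$b_i)
  }))
  pooled <- fit_species(plants)
  expect_gte(pooled$a, min(per[, 1])); expect_lte(pooled$a, max(per[, 1]))
  expect_gte(pooled$b, min(per[, 2])); expect_lte(pooled$b, max(per[, 2]))
})

test_that("pooled fit recovers generating constants from noisy pots", {
  cfg <- sim_config("maize", seed = 21)
  fit <- fit_species(simulate_pot(cfg))
  # the self-normalised generator's effective intercept is exp(-b)
  expect_lt(abs(fit$b - 2.028), 0.1)
  expect_lt(abs(fit$a - exp(-2.028)), 0.015)
  # REML route lands close to the two-stage route
  fit2 <- fit_species(simulate_pot(cfg, seed = 21), method = "reml")
  expect_lt(abs(fit$b - fit2$b), 0.08)
})

test_that("species mixing is rejected", {
  m <- exact_series(0.13, 2.028)
  s <- exact_series(0.244, 1.392, species = "soybean", plant_id = "S1")
  expect_error(fit_species(list(m, s)), "single species")
})

test_that("mass calibration fits the linear RDM relation", {
  rdm <- c(0.5, 2, 4, 7, 11)
  fit <- fit_mass_calibration(3 * rdm + 1, rdm, condition = "saturated")
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  expect_error(fit_mass_calibration(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(fit_mass_calibration(c(1, 2, 3), c(2, 2, 2)),
               "zero variance")
})

test_that("synthetic harvests give mass calibrations of realistic strength", {
  r2s <- sapply(1:20, function(s) {
    pots <- simulate_pot(sim_config("maize"), seed = 300 + s)
    rdm <- sapply(pots, `[[`, "rdm")
    c_sat <- sapply(pots, `[[`, "c_r_sat")
    fit_mass_calibration(c_sat, rdm)$r2
  })
  # n = 15 plants gives R2 a wide sampling spread: assert central strength
  expect_gt(median(r2s), 0.75)
  expect_lt(median(r2s), 0.95)
  expect_true(all(r2s > 0.4))
})

test_that("soil power law is recovered exactly from noise-free data", {
  theta <- seq(0.25, 1, length.out = 20)
  m <- fit_soil_model(theta, 350.3 * theta^1.086)
  expect_equal(m$coeff, 350.3, tolerance = 1e-9)
  expect_equal(m$expnt, 1.086, tolerance = 1e-9)
  # the fitted curve at saturation matches the saturated-soil mean
  expect_lt(abs(predict_soil_capacitance(m, 1) - 346.3), 14.2)
  expect_error(fit_soil_model(c(-0.1, 0.5), c(10, 20)), "positive")
})

test_that("effect screen demands two distinct species and known ages", {
  m <- simulate_pot(sim_config("maize", seed = 2))
  expect_error(test_age_species_effects(m, m), "two distinct species")
  s_const_age <- lapply(simulate_pot(sim_config("soybean", seed = 2)),
                        function(x) { x$age_days <- 30L; x })
  expect_warning(scr <- test_age_species_effects(m, s_const_age),
                 "age terms dropped")
  expect_false("age" %in% scr$joint$factor)
  expect_true(scr$joint$significant[scr$joint$factor == "species"])
})
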