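test_that("day summaries report mean, sample SD and CV", {
  s <- summarize_day(c(1, 2, 3), das = 78)
  expect_equal(s$mean_c_r_star, 2)
  expect_equal(s$sd_c_r_star, 1)       # n - 1 denominator
  expect_equal(s$cv_pct, 50)

  s0 <- summarize_day(c(4, 4, 4, 4))
  expect_equal(s0$sd_c_r_star, 0)
  expect_equal(s0$cv_pct, 0)

  expect_error(summarize_day(5), "n >= 2")
})

test_that("simulated within-day theta variability matches the campaign", {
  # maize DAS-78 day at reference parameters: theta CV inside the
  # campaign-wide 8.2-12.5% band in most replicates
  cfg <- sim_config("maize")
  cvs <- sapply(1:20, function(s) {
    fld <- simulate_field(cfg, seed = 400 + s)$readings
    d <- fld[fld$das == 78, ]
    100 * sd(d$theta_rel) / mean(d$theta_rel)
  })
  expect_gt(mean(cvs >= 8.2 & cvs <= 12.5 + 2), 0.8)
})

test_that("star assignment is a strict threshold function of p", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.05, 0.2)),
               c("***", "**", "*", "NS", "NS"))
})

test_that("poolability check behaves as a one-way ANOVA gate", {
  # identical copies: no evidence against pooling
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- check_poolability(g)
  expect_true(res$details$poolable)
  expect_gt(res$p_value, 0.99)

  # one group shifted by 5 SDs: clearly not poolable
  set.seed(1)
  g2 <- list(rnorm(16, 10, 1), rnorm(16, 10, 1), rnorm(16, 15, 1))
  res2 <- check_poolability(g2)
  expect_false(res2$details$poolable)
  expect_lt(res2$p_value, 0.001)

  expect_error(check_poolability(list(c(1, 2))), ">= 2 groups")
  expect_error(check_poolability(list(c(1, 2), 3)), "n >= 2")
})

test_that("null groups are pooled at roughly the nominal rate", {
  set.seed(99)
  rej <- sum(replicate(400, {
    g <- split(rnorm(48, 10, 1), rep(1:3, each = 16))
    !check_poolability(g)$details$poolable
  }))
  # Binomial(400, 0.05): mean 20, sd 4.4; allow ~3.5 sd
  expect_gte(rej, 5)
  expect_lte(rej, 36)
})

test_that("consecutive-day comparison is symmetric and honest on nulls", {
  x <- c(10.2, 11.4, 9.8, 10.9, 10.1)
  res <- compare_consecutive(x, x)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_equal(res$significance_stars, "NS")

  set.seed(7)
  a <- rnorm(48, 10, 1); b <- rnorm(48, 14, 1.2)
  expect_equal(compare_consecutive(a, b)$p_value,
               compare_consecutive(b, a)$p_value)
})

test_that("variance pre-test routes to Welch when SDs differ", {
  set.seed(12)
  a <- rnorm(48, 10, 1)
  b <- rnorm(48, 10, 3)     # SD tripled
  res <- compare_consecutive(a, b)
  expect_equal(res$test_used, "welch_t")
  # oracle: the branch must agree with the F-test decision
  expect_lt(res$details$var_test_p, 0.05)

  b2 <- rnorm(48, 12, 1)
  res2 <- compare_consecutive(a, b2)
  expect_equal(res2$test_used, "t")
  expect_gte(res2$details$var_test_p, 0.05)
})

test_that("consecutive campaign days differ highly significantly", {
  cfg <- sim_config("maize")
  cal <- species_constants("maize")
  hits <- sapply(1:20, function(s) {
    nc <- normalize_campaign(simulate_field(cfg, seed = 500 + s)$readings,
                             cal)
    compare_consecutive(nc$c_r_star[nc$das == 36],
                        nc$c_r_star[nc$das == 50])$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("treatment comparison detects a 5% uplift and respects the null", {
  set.seed(31)
  sig <- replicate(40, {
    con <- rlnorm(48, log(7.20), 0.09)       # CV ~9%
    ino <- rlnorm(48, log(7.20 * 1.05), 0.09)
    compare_treatments(con, ino)$p_value < 0.05
  })
  expect_gt(mean(sig), 0.5)                   # majority of runs

  null_ns <- replicate(40, {
    con <- rlnorm(48, log(7.20), 0.09)
    ino <- rlnorm(48, log(7.20), 0.09)
    compare_treatments(con, ino)$significance_stars == "NS"
  })
  expect_gte(mean(null_ns), 0.9)
})

test_that("multi-group comparison selects its branch by Bartlett", {
  set.seed(5)
  equal_var <- list(a = rnorm(18, 10, 1), b = rnorm(18, 11, 1),
                    c = rnorm(10, 12, 1))   # unequal n: Tukey-Kramer
  res <- compare_groups(equal_var)
  expect_equal(res$test_used, "anova_tukey")
  expect_equal(nrow(res$details$posthoc), 3)

  het_var <- list(a = rnorm(18, 10, 0.5), b = rnorm(18, 10, 0.5),
                  c = rnorm(18, 10, 4))
  res2 <- compare_groups(het_var)
  expect_equal(res2$test_used, "kruskal_dunn")
  expect_lt(res2$details$bartlett_p, 0.05)

  expect_error(compare_groups(list(1:5, 6:10)), ">= 3 groups")
})

test_that("Dunn's test matches hand-computed rank statistics", {
  # no ties, balanced: z for a pair is (R1 - R2) / sqrt(N(N+1)/12 * 2/n)
  values <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_test(values, g)
  n <- 9
  se <- sqrt(n * (n + 1) / 12 * (2 / 3))
  z_ab <- (mean(rank(values)[1:3]) - mean(rank(values)[4:6])) / se
  got <- d$z[d$group1 == "a" & d$group2 == "b"]
  expect_equal(unname(got), z_ab, tolerance = 1e-12)
  expect_equal(d$p_value[1], min(1, 2 * pnorm(-abs(z_ab)) * 3),
               tolerance = 1e-12)
})

test_that("within-day regression recovers the moisture dependence", {
  cfg <- sim_config("maize")
  fld <- simulate_field(cfg, seed = 61)$readings
  d <- fld[fld$das == 78, ]
  reg <- day_cr_theta_regression(d)
  expect_gt(reg$b_day, 0)
  expect_lt(reg$p, 0.01)
  expect_gt(reg$r2, 0.3); expect_lt(reg$r2, 0.9)

  # noise-free day: perfect fit
  theta <- seq(0.25, 0.6, length.out = 12)
  exact <- data.frame(theta_rel = theta,
                      c_r_nf = 5 * 0.13 * exp(2.028 * theta))
  expect_equal(day_cr_theta_regression(exact)$r2, 1, tolerance = 1e-10)

  const <- data.frame(theta_rel = rep(0.4, 10), c_r_nf = rlnorm(10))
  expect_error(day_cr_theta_regression(const), "degenerate")
  expect_error(day_cr_theta_regression(exact[1:3, ]), "n >= 5")
})

test_that("pooling homogeneous groups barely moves the day mean", {
  cfg <- sim_config("maize")
  cal <- species_constants("maize")
  nc <- normalize_campaign(simulate_field(cfg, seed = 71)$readings, cal)
  d <- nc[nc$das == 92, ]
  pooled_mean <- mean(d$c_r_star)
  by_group <- tapply(d$c_r_star, d$group, mean)
  expect_lt(abs(mean(by_group) - pooled_mean) / pooled_mean, 0.001)
})
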