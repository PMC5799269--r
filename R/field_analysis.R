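# Field statistics stage: poolability checks, per-day summaries,
# consecutive-day and treatment comparisons (with variance-equality
# pre-tests selecting the parametric branch), per-day capacitance-moisture
# regressions, and harvest group comparisons.

#' Significance stars
#'
#' Maps a p-value onto the conventional star code with strict cutoffs:
#' \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05, otherwise
#' \code{NS} (so p = 0.05 exactly is NS).
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "NS")))
}

.comparison_result <- function(kind, statistic, p_value, test_used,
                               details = NULL) {
  structure(list(kind = kind, statistic = unname(statistic),
                 p_value = unname(p_value), test_used = test_used,
                 significance_stars = p_stars(p_value), details = details),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s comparison [%s]: statistic = %.4g, p = %.4g (%s)\n",
              x$kind, x$test_used, x$statistic, x$p_value,
              x$significance_stars))
  invisible(x)
}

#' Per-day summary of normalized field readings
#'
#' @param c_star Apparent capacitances of one measurement day, nF, n >= 2.
#' @param theta Matching theta_rel values (optional).
#' @param das Days after sowing.
#' @param treatment Treatment label.
#' @param bbch BBCH phenology code (optional).
#' @return One-row data frame: \code{das}, \code{treatment}, \code{n},
#'   \code{mean_c_r_star}, \code{sd_c_r_star}, \code{cv_pct} (100 * sd /
#'   mean), \code{mean_theta}, \code{sd_theta}, \code{bbch}. SDs use the
#'   n - 1 denominator.
#' @export
summarize_day <- function(c_star, theta = NULL, das = NA_integer_,
                          treatment = "none", bbch = NA_integer_) {
  if (length(c_star) < 2L)
    stop("need n >= 2 readings to summarise a day", call. = FALSE)
  data.frame(
    das = as.integer(das), treatment = treatment, n = length(c_star),
    mean_c_r_star = mean(c_star), sd_c_r_star = stats::sd(c_star),
    cv_pct = 100 * stats::sd(c_star) / mean(c_star),
    mean_theta = if (is.null(theta)) NA_real_ else mean(theta),
    sd_theta = if (is.null(theta)) NA_real_ else stats::sd(theta),
    bbch = as.integer(bbch))
}

#' Summarise a normalized campaign by day (and treatment)
#'
#' @param normalized Output of \code{\link{normalize_campaign}}.
#' @return A data frame of \code{\link{summarize_day}} rows, ordered by
#'   das then treatment.
#' @export
summarize_campaign <- function(normalized) {
  stopifnot("c_r_star" %in% names(normalized))
  pieces <- split(normalized,
                  list(normalized$das, normalized$treatment), drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d)
    summarize_day(d$c_r_star, d$theta_rel, das = d$das[1],
                  treatment = d$treatment[1],
                  bbch = if ("bbch" %in% names(d)) d$bbch[1] else NA)))
  out <- out[order(out$das, out$treatment), ]
  rownames(out) <- NULL
  out
}

#' Poolability check across replicate groups
#'
#' One-way ANOVA across replicate row-segments or plots; pooling the groups
#' into one sample is recommended iff the group effect is not significant
#' (p >= alpha).
#'
#' @param groups List of >= 2 numeric vectors, each n >= 2.
#' @param alpha Significance threshold (default 0.05).
#' @return A \code{comparison_result} (kind "multi_group") whose
#'   \code{details$poolable} flags the recommendation.
#' @export
check_poolability <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0) {
    # identical constant groups: no evidence against pooling
    return(.comparison_result("multi_group", 0, 1, "anova_tukey",
                              details = list(poolable = TRUE)))
  }
  an <- stats::anova(stats::lm(values ~ g))
  p <- an$`Pr(>F)`[1]
  .comparison_result("multi_group", an$`F value`[1], p, "anova_tukey",
                     details = list(poolable = p >= alpha))
}

# Two-sample core: F-test on variances picks Student vs Welch.
.two_sample <- function(x, y, kind, alpha_var = 0.05) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need n >= 2", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    return(.comparison_result(kind, 0, p, "t"))
  }
  var_p <- stats::var.test(x, y)$p.value
  equal_var <- var_p >= alpha_var
  tt <- stats::t.test(x, y, var.equal = equal_var)
  .comparison_result(kind, tt$statistic, tt$p.value,
                     if (equal_var) "t" else "welch_t",
                     details = list(var_test_p = var_p))
}

#' Compare two consecutive measurement days
#'
#' Two-sided two-sample comparison of C_R* between consecutive field
#' measurement days. An F-test on the two variances (at alpha = 0.05)
#' selects Student's t when variances are compatible and Welch's t
#' otherwise.
#'
#' @param day_a,day_b Numeric vectors of per-plant C_R* for the two days.
#' @return A \code{comparison_result} (kind "consecutive_day").
#' @export
compare_consecutive <- function(day_a, day_b) {
  .two_sample(day_a, day_b, "consecutive_day")
}

#' Compare control and inoculated treatment groups
#'
#' Same two-sample machinery as \code{\link{compare_consecutive}}, applied
#' to CON vs INO readings of one measurement day (C_R*, theta_rel, SDM or
#' M%).
#'
#' @param con,ino Numeric vectors for the two treatments.
#' @return A \code{comparison_result} (kind "treatment").
#' @export
compare_treatments <- function(con, ino) {
  .two_sample(con, ino, "treatment")
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction, Bonferroni
#' adjusted. Used when the variance-equality pre-test rejects and >= 3
#' groups must be compared.
#'
#' @param values Numeric vector of all observations.
#' @param g Factor of group labels, same length.
#' @return A data frame with columns \code{group1}, \code{group2}, \code{z},
#'   \code{p_value} (Bonferroni-adjusted, capped at 1).
#' @export
dunn_test <- function(values, g) {
  g <- factor(g)
  if (nlevels(g) < 3L) stop("Dunn's test needs >= 3 groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_value = NA_real_)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[i1] + 1 / ns[i2]))
    z <- (mean_ranks[i1] - mean_ranks[i2]) / se
    out$z[j] <- z
    out$p_value[j] <- min(1, 2 * stats::pnorm(-abs(z)) * m)
  }
  out
}

#' Multi-group comparison with automatic branch selection
#'
#' For >= 3 groups (e.g. harvest SDM or AMF colonization across plots):
#' Bartlett's test on variances (alpha = 0.05) selects either one-way
#' ANOVA with the Tukey-Kramer post-test (variances compatible; Tukey-Kramer
#' because group sizes may differ) or Kruskal-Wallis with Dunn's
#' Bonferroni-adjusted post-test.
#'
#' @param groups Named list of >= 3 numeric vectors (n >= 2 each).
#' @param alpha_var Pre-test threshold (default 0.05).
#' @return A \code{comparison_result} (kind "multi_group",
#'   \code{test_used} "anova_tukey" or "kruskal_dunn") whose
#'   \code{details$posthoc} is the pairwise table.
#' @export
compare_groups <- function(groups, alpha_var = 0.05) {
  if (length(groups) < 3L)
    stop("compare_groups needs >= 3 groups (use compare_treatments for 2)",
         call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  bart_p <- stats::bartlett.test(values, g)$p.value
  if (bart_p >= alpha_var) {
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_value = tk[, "p adj"], row.names = NULL)
    .comparison_result("multi_group", an$`F value`[1], an$`Pr(>F)`[1],
                       "anova_tukey",
                       details = list(bartlett_p = bart_p,
                                      posthoc = posthoc))
  } else {
    kw <- stats::kruskal.test(values, g)
    posthoc <- dunn_test(values, g)
    .comparison_result("multi_group", kw$statistic, kw$p.value,
                       "kruskal_dunn",
                       details = list(bartlett_p = bart_p,
                                      posthoc = posthoc))
  }
}

#' Within-day exponential C_R-theta_rel regression
#'
#' Across the plants of one measurement day, fits C_R = a_day *
#' exp(b_day * theta_rel) by OLS of log(C_R) on theta_rel. In a healthy
#' campaign the within-day moisture heterogeneity alone produces a positive,
#' significant slope — the same moisture dependence the calibration
#' quantifies in pots.
#'
#' @param readings Data frame with \code{theta_rel} and \code{c_r_nf} for
#'   one day, n >= 5 with non-degenerate theta spread.
#' @return A list: \code{a_day}, \code{b_day}, \code{r2}, \code{p} (slope
#'   p-value), \code{n}.
#' @export
day_cr_theta_regression <- function(readings) {
  if (nrow(readings) < 5L)
    stop("need n >= 5 readings for a within-day regression", call. = FALSE)
  if (stats::var(readings$theta_rel) == 0)
    stop("degenerate theta_rel spread: regression undefined", call. = FALSE)
  fit <- stats::lm(log(c_r_nf) ~ theta_rel, data = readings)
  st <- .lm_stats(fit)
  list(a_day = exp(unname(stats::coef(fit)[1])),
       b_day = unname(stats::coef(fit)[2]),
       r2 = st$r2,
       p = unname(st$p[2]),
       n = nrow(readings))
}
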