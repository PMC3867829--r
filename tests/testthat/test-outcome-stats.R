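# NDS scoring and the outcome-statistics layer.

test_that("NDS totals span 0-500 and the validator names offending categories", {
  cats <- names(nds_categories())
  zeros <- setNames(rep(0, 7), cats)
  expect_equal(nds_total(zeros), 0)
  maxima <- vapply(nds_categories(), max, numeric(1))
  expect_equal(nds_total(maxima), 500)
  expect_equal(nds_total(c(consciousness = 50, respiration = 0,
                           cornea_reflex = 20, cranial_reflex = 0,
                           auditory_reflex = 15, motor_sensory = 50,
                           behavior = 50)), 185)
  bad <- zeros; bad["cornea_reflex"] <- 25
  expect_error(nds_total(bad), "cornea_reflex")
  expect_error(nds_total(zeros[-3]), "missing")
})

test_that("Welch t from summaries handles the zero-variance and degenerate cases", {
  same <- welch_t_summary(5, 1, 10, 5, 1, 10)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # one zero-variance group reduces df to n_other - 1
  one0 <- welch_t_summary(204, 254.8, 10, 500, 0, 10)
  expect_equal(unname(one0$parameter), 9)
  expect_warning(both0 <- welch_t_summary(1, 0, 5, 2, 0, 5), "zero")
  expect_equal(both0$p.value, 0)
  expect_equal(welch_t_summary(1, 0, 5, 1, 0, 5)$p.value, 1)
  expect_error(welch_t_summary(1, 1, 1, 2, 1, 5), ">= 2")
})

test_that("raw-sample Welch t equals the summary form and the reference implementation", {
  set.seed(41)
  for (k in 1:20) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    mine <- welch_t_raw(x, y)
    via_summary <- welch_t_summary(mean(x), sd(x), length(x),
                                   mean(y), sd(y), length(y))
    expect_identical(mine$p.value, via_summary$p.value)
    ref <- t.test(x, y)  # independent route: stats::t.test Welch form
    expect_equal(unname(mine$statistic), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    pooled <- welch_t_raw(x, y, pooled = TRUE)
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$p.value, ref_p$p.value, tolerance = 1e-12)
  }
  expect_identical(welch_t_raw(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(welch_t_raw(c(1, 2, 3), c(4, 5, 6))$p.value,
               welch_t_summary(2, 1, 3, 5, 1, 3)$p.value)
})

test_that("Fisher's exact test matches exhaustive enumeration and symmetry", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p.value, 1)
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p.value, 1)  # empty margin
  # spot grid of tables against the enumeration oracle
  for (a in 0:4) for (b in 0:3) for (cc in 0:4) for (d in 0:3) {
    expect_equal(fisher_exact_2x2(a, b, cc, d)$p.value,
                 fisher_enum(a, b, cc, d), tolerance = 1e-9,
                 label = sprintf("table %d %d %d %d", a, b, cc, d))
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "integer")
})

test_that("Spearman correlation uses midranks and the t approximation", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(x, -x)$p.value, 0)
  set.seed(55)
  for (k in 1:10) {
    a <- sample(1:5, 12, replace = TRUE)  # heavy ties
    b <- a + sample(-1:1, 12, replace = TRUE)
    sc <- spearman_cor(a, b)
    expect_equal(sc$rho, cor(a, b, method = "spearman"), tolerance = 1e-12)
    expect_equal(sc$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
    if (abs(sc$rho) < 1) {
      tref <- sc$rho * sqrt((12 - 2) / (1 - sc$rho^2))
      expect_equal(sc$statistic, tref)
    }
  }
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("single-predictor logistic regression recovers effects and flags separation", {
  # symmetric balanced data -> intercept ~ 0
  x <- c(-2, -1, -1, 1, 1, 2)
  y <- c(0, 1, 0, 1, 0, 1)
  fit <- logistic_single(x, y)
  expect_lt(abs(fit$intercept), 1e-6)
  expect_false(fit$separated)
  expect_equal(fit$predict(0), 0.5, tolerance = 1e-6,
               ignore_attr = TRUE)

  # parameter recovery: positive configured effect -> positive slope >= 95%
  set.seed(66)
  signs <- replicate(200, {
    xx <- rnorm(40)
    yy <- rbinom(40, 1, plogis(0.3 + 1.5 * xx))
    if (length(unique(yy)) < 2) return(NA)
    sign(logistic_single(xx, yy)$slope)
  })
  expect_gte(mean(signs == 1, na.rm = TRUE), 0.95)

  # complete separation is flagged
  xs <- c(-3, -2, -1, 1, 2, 3)
  ys <- c(0, 0, 0, 1, 1, 1)
  expect_true(logistic_single(xs, ys)$separated)
  expect_error(logistic_single(1:6, rep(1, 6)), "both classes")
})

test_that("logistic slope Wald p is calibrated under the null", {
  set.seed(67)
  p <- replicate(400, {
    xx <- rnorm(60)
    yy <- rbinom(60, 1, 0.5)
    logistic_single(xx, yy)$p.value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Kaplan-Meier estimates reproduce the survival-table fractions", {
  # treated arm: alive 10, 8, 6, 6 at 24/48/72/96 h; survivors censored at 96
  t1 <- c(48, 48, 72, 72, rep(96, 6))
  e1 <- c(1, 1, 1, 1, rep(0, 6))
  # control arm: alive 8, 2, 0 at 24/48/72 h
  t2 <- c(24, 24, rep(48, 6), 72, 72)
  e2 <- rep(1, 10)
  km <- km_logrank(c(t1, t2), c(e1, e2), rep(c("treated", "control"), each = 10))
  expect_equal(km$surv_at(96, "treated"), 0.6, tolerance = 1e-9)
  expect_equal(km$surv_at(72, "control"), 0, tolerance = 1e-9)
  expect_lt(km$p.value, 0.05)

  # identical groups -> log-rank statistic ~ 0
  km0 <- km_logrank(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 10))
  expect_lt(km0$chisq, 1e-9)

  # no censoring: KM equals the empirical survival function
  tt <- c(10, 20, 30, 40)
  km2 <- km_logrank(c(tt, tt + 5), rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(km2$surv_at(25, "a"), mean(tt > 25), tolerance = 1e-9)
  expect_equal(km2$surv_at(40, "a"), 0, tolerance = 1e-9)
})

test_that("two-way ANOVA sums of squares match the hand decomposition on a balanced layout", {
  # 2 groups x 2 times, 3 obs per cell
  d <- expand.grid(rep = 1:3, group = c("g1", "g2"), time = c("t1", "t2"))
  d$y <- c(1, 2, 3, 4, 5, 6, 2, 3, 4, 8, 9, 10)
  res <- twoway_anova_posthoc(d$y, d$group, d$time)
  # hand decomposition for the balanced two-factor design
  gm <- mean(d$y)
  ss_group <- sum(tapply(d$y, d$group, function(v) length(v) * (mean(v) - gm)^2))
  ss_time <- sum(tapply(d$y, d$time, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(d$y, list(d$group, d$time), mean)
  ss_cells <- 3 * sum((cellm - gm)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_res <- sum((d$y - ave(d$y, d$group, d$time))^2)
  expect_equal(res$anova["group", "Sum Sq"], ss_group)
  expect_equal(res$anova["time", "Sum Sq"], ss_time)
  expect_equal(res$anova["group:time", "Sum Sq"], ss_int)
  expect_equal(res$anova["Residuals", "Sum Sq"], ss_res)
  expect_identical(nrow(res$posthoc), 2L)
})

test_that("two-way ANOVA post hoc behaves under null and graded effects", {
  set.seed(91)
  base <- expand.grid(id = 1:8, group = c("g1", "g2"), time = c("t1", "t2", "t3"))
  # identical groups: group F small, post hoc p large
  y0 <- rnorm(nrow(base))
  y0 <- y0 - ave(y0, base$group)  # remove any group difference exactly
  res0 <- twoway_anova_posthoc(y0, base$group, base$time)
  expect_lt(res0$anova["group", "F value"], 1e-20)
  # additive effect: group F grows monotonically with effect size
  fvals <- vapply(c(0.5, 1.5, 3), function(eff) {
    y <- y0 + eff * (base$group == "g2")
    twoway_anova_posthoc(y, base$group, base$time)$anova["group", "F value"]
  }, numeric(1))
  expect_true(all(diff(fvals) > 0))
  # empty cell handling
  sel <- !(base$group == "g1" & base$time == "t3")
  expect_warning(
    res <- twoway_anova_posthoc(y0[sel], base$group[sel], base$time[sel]),
    "excluded")
  expect_identical(nrow(res$posthoc), 2L)
})
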