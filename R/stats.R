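# Outcome-statistics layer: two-sample tests from raw or summary data,
# Fisher's exact test, Spearman correlation, single-predictor logistic
# regression, Kaplan-Meier + log-rank, and two-way ANOVA with per-time
# post hoc comparisons.

#' Two-sample t test from summary statistics
#'
#' Computes the two-sided two-sample t test directly from group means,
#' standard deviations and sizes. The default is the unequal-variance (Welch)
#' form with Satterthwaite degrees of freedom; `pooled = TRUE` gives the
#' classical equal-variance form. When exactly one group has zero variance
#' the Satterthwaite formula reduces to `n - 1` degrees of freedom of the
#' other group. When both variances are zero the p value is 1 if the means
#' are equal and 0 (with a warning) otherwise.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param pooled Use the pooled-variance (Student) form instead of Welch.
#' @return An object of class `htest` with `statistic` (t), `parameter`
#'   (df) and `p.value`.
#' @examples
#' welch_t_summary(15.1, 1.9, 10, 21.5, 6.0, 10)  # p ~ 0.008
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both group sizes must be >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  est <- m1 - m2
  if (s1 == 0 && s2 == 0) {
    if (est == 0) {
      t <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      warning("both standard deviations are zero and the means differ; p = 0")
      t <- sign(est) * Inf; df <- n1 + n2 - 2; p <- 0
    }
  } else if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- est / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    t <- est / sqrt(v1 + v2)
    df <- if (s1 == 0) n2 - 1
          else if (s2 == 0) n1 - 1
          else (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(
    statistic = c(t = t), parameter = c(df = df), p.value = p,
    estimate = c(`difference in means` = est),
    alternative = "two.sided",
    method = if (pooled) "Two-sample t test (pooled variance, from summaries)"
             else "Welch two-sample t test (from summaries)",
    data.name = sprintf("group 1 (m=%g, s=%g, n=%d) vs group 2 (m=%g, s=%g, n=%d)",
                        m1, s1, n1, m2, s2, n2)),
    class = "htest")
}

#' Two-sample t test from raw samples
#'
#' Identical, by construction, to [welch_t_summary()] applied to the two
#' samples' own mean, SD and size.
#'
#' @param x,y Numeric samples of size >= 2.
#' @param pooled Use the pooled-variance form.
#' @return An object of class `htest`.
#' @export
welch_t_raw <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both samples must have at least 2 observations", call. = FALSE)
  welch_t_summary(mean(x), stats::sd(x), length(x),
                  mean(y), stats::sd(y), length(y), pooled = pooled)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test with fixed margins; the two-sided p value is the sum
#' of the hypergeometric probabilities of all tables no more probable than
#' the observed one (the sum-of-smaller-probabilities rule).
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return An object of class `htest`.
#' @examples
#' fisher_exact_2x2(6, 4, 0, 10)  # p ~ 0.011
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  tab <- matrix(as.integer(cells), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(
      statistic = NULL, p.value = 1,
      estimate = NULL, alternative = "two.sided",
      method = "Fisher's exact test for a 2x2 table (degenerate margin)",
      data.name = paste(cells, collapse = ", ")), class = "htest"))
  }
  res <- stats::fisher.test(tab, alternative = "two.sided")
  res$data.name <- paste(cells, collapse = ", ")
  res
}

#' Spearman rank correlation with t-approximation p value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' two-sided p value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric samples, `n >= 4`.
#' @return A list with `rho`, `statistic`, `df`, `p.value`, `n`. For constant
#'   input `rho` is undefined and returned as `NA`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, statistic = NA_real_, df = n - 2L,
                p.value = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    t <- sign(rho) * Inf; p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, statistic = t, df = n - 2L, p.value = p, n = n)
}

#' Single-predictor logistic regression
#'
#' Maximum-likelihood fit of `logit P(outcome = 1) = intercept + slope *
#' predictor`, with a Wald test on the slope. Complete or quasi-complete
#' separation is detected (fitted probabilities numerically at 0/1) and
#' flagged rather than reported as a converged fit.
#'
#' @param predictor Numeric predictor.
#' @param outcome Binary outcome (0/1 or logical); both classes must occur.
#' @return A list with `intercept`, `slope`, `slope_se`, `wald_z`,
#'   `p.value`, `converged`, `separated`, the fitted `model`, and
#'   `predict(newx)` giving fitted probabilities.
#' @export
logistic_single <- function(predictor, outcome) {
  ok <- stats::complete.cases(predictor, outcome)
  x <- predictor[ok]; y <- as.integer(outcome[ok])
  if (length(x) < 6) stop("need at least 6 observations", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes", call. = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  eps <- 1e-8
  separated <- !fit$converged ||
    all(fit$fitted.values[y == 1] > 1 - eps) && all(fit$fitted.values[y == 0] < eps)
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       slope_se = unname(co[2, 2]), wald_z = unname(co[2, 3]),
       p.value = unname(co[2, 4]),
       converged = fit$converged, separated = separated, model = fit,
       predict = function(newx)
         stats::predict(fit, newdata = data.frame(x = newx), type = "response"))
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group (censoring supported; in the
#' standard design animals alive at 96 h are censored there) and the log-rank
#' chi-square test on one degree of freedom, with the standard tied-risk-set
#' handling.
#'
#' @param time Follow-up times (hours).
#' @param event Death indicator (1 = died, 0 = censored).
#' @param group Two-level grouping factor.
#' @return A list with the `survival::survfit` object (`fit`), `chisq`,
#'   `df`, `p.value`, and `surv_at(t, group)` returning the estimated
#'   survival fraction at time `t`. With no events anywhere the log-rank
#'   statistic is undefined (`NA`).
#' @export
km_logrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("'group' must have exactly 2 levels", call. = FALSE)
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  df <- data.frame(time = time, event = as.integer(event), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(df$event) == 0) {
    chisq <- NA_real_; p <- NA_real_
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- unname(sd_$chisq)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  surv_at <- function(t, g) {
    g <- as.character(g)
    s <- summary(fit, times = t, extend = TRUE)
    lev <- sub("^group=", "", as.character(s$strata))
    s$surv[lev == g]
  }
  list(fit = fit, chisq = chisq, df = 1L, p.value = p, surv_at = surv_at)
}

#' Two-way ANOVA (group x time) with per-time post hoc tests
#'
#' Fits the two-factor linear model `value ~ group * time` (both treated as
#' factors) and reports the ANOVA table (sequential sums of squares) together
#' with per-time-point two-sample comparisons as post hoc tests. Post hoc p
#' values are unadjusted by default; `adjust` selects a [stats::p.adjust()]
#' method.
#'
#' @param value Numeric response, one observation per animal per time point.
#' @param group Two-level grouping factor.
#' @param time Time factor (or values coercible to factor).
#' @param adjust Multiplicity adjustment for the post hoc p values
#'   (default `"none"`).
#' @param pooled Use pooled-variance post hoc t tests instead of Welch.
#' @return A list with `anova` (the table) and `posthoc` (a `data.frame`
#'   with `time`, `t`, `df`, `p.value`, `p.adjusted`). Time points with an
#'   empty cell are excluded with a warning.
#' @export
twoway_anova_posthoc <- function(value, group, time, adjust = "none",
                                 pooled = FALSE) {
  group <- factor(group)
  time <- factor(time)
  if (nlevels(group) != 2) stop("'group' must have exactly 2 levels", call. = FALSE)
  keep_t <- levels(time)[vapply(levels(time), function(tl)
    all(table(group[time == tl]) > 0) && sum(time == tl) > 0, logical(1))]
  if (length(keep_t) < nlevels(time))
    warning("time points with an empty group cell excluded: ",
            paste(setdiff(levels(time), keep_t), collapse = ", "))
  sel <- time %in% keep_t
  d <- data.frame(value = value[sel], group = droplevels(group[sel]),
                  time = droplevels(time[sel]))
  fit <- stats::lm(value ~ group * time, data = d)
  atab <- stats::anova(fit)
  ph <- do.call(rbind, lapply(levels(d$time), function(tl) {
    x <- d$value[d$time == tl & d$group == levels(d$group)[1]]
    y <- d$value[d$time == tl & d$group == levels(d$group)[2]]
    res <- welch_t_raw(x, y, pooled = pooled)
    data.frame(time = tl, t = unname(res$statistic),
               df = unname(res$parameter), p.value = res$p.value)
  }))
  ph$p.adjusted <- stats::p.adjust(ph$p.value, method = adjust)
  list(anova = atab, posthoc = ph, model = fit)
}
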