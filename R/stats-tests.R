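#' Unpaired t-tests for probe-day group comparisons
#'
#' Compares a probe-day (test-day) metric between groups with unpaired
#' two-sided t-tests, one row per pair of groups. Pooled-variance tests are
#' the default; Welch's correction is available via `welch = TRUE`.
#'
#' Degenerate inputs are handled explicitly rather than erroring: when both
#' groups have zero variance the p-value is 1 for equal means and 0 for
#' unequal means, and the row is flagged `degenerate`.
#'
#' @param data A data frame of per-animal metrics.
#' @param value Column holding the metric (tidy-eval).
#' @param group Column holding the group label (tidy-eval).
#' @param welch Use Welch's unequal-variance t-test instead of pooled.
#' @return A tibble with one row per group pair: group labels, per-group n
#'   and means, `estimate` (mean difference a - b), `t`, `df`, `p`,
#'   `degenerate`.
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("tg", "ntg"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' day5_tests(d, y, g)
day5_tests <- function(data, value, group, welch = FALSE) {
  check_flag(welch, "welch")
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  df <- tibble(
    g = as.character(dplyr::pull(data, !!group)),
    y = as.numeric(dplyr::pull(data, !!value))
  )
  df <- df[is.finite(df$y), , drop = FALSE]
  gs <- sort(unique(df$g))
  if (length(gs) < 2L) abort_field("group", "need at least two groups")
  pairs <- utils::combn(gs, 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- df$y[df$g == pr[1]]
    b <- df$y[df$g == pr[2]]
    res <- two_sample_t(a, b, welch = welch)
    tibble(
      group_a = pr[1], group_b = pr[2],
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      estimate = mean(a) - mean(b),
      t = res$t, df = res$df, p = res$p,
      degenerate = res$degenerate
    )
  })
}

two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_field("data", "need n >= 2 per group")
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' One-sample test against a chance level
#'
#' Two-sided one-sample t-test of the mean of `values` against a fixed
#' chance constant, e.g. 25 (% abidance in the target quadrant) or 1.5
#' (target-zone crossings) on the probe day.
#'
#' @param values Numeric vector of per-animal values (n >= 2).
#' @param chance Chance-level constant to test against.
#' @return A one-row tibble: `n`, `mean`, `chance`, `t`, `df`, `p`,
#'   `degenerate` (TRUE when the sample SD is zero).
#' @export
chance_level_test <- function(values, chance) {
  check_scalar_num(chance, "chance")
  values <- values[is.finite(values)]
  if (length(values) < 2L) abort_field("values", "need n >= 2")
  if (sd(values) == 0) {
    eq <- isTRUE(all.equal(mean(values), chance))
    return(tibble(n = length(values), mean = mean(values), chance = chance,
                  t = if (eq) 0 else sign(mean(values) - chance) * Inf,
                  df = length(values) - 1,
                  p = if (eq) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = chance)
  tibble(n = length(values), mean = mean(values), chance = chance,
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, degenerate = FALSE)
}

#' Cohen's d effect size for two groups
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, pooling the
#' group variances with n - 1 weights. Positive d means group a has the
#' larger mean.
#'
#' @param group_a,group_b Numeric vectors, n >= 2 each.
#' @return A single number; `NA` with a warning if the pooled SD is zero.
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) abort_field("data", "need n >= 2 per group")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    warning("pooled SD is zero; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Pearson correlation with regression summary
#'
#' Pearson's r with a two-sided p-value from the t-distribution (n - 2 df),
#' together with the simple least-squares regression of y on x evaluated on
#' the same pairs: slope, intercept, R-squared (equal to r^2) and the mean
#' squared residual (MSE, residual sum of squares / n).
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped; n >= 3 complete pairs required.
#' @return An object of class `corr_result` (a one-row tibble with columns
#'   `r`, `p`, `n`, `r_squared`, `mse`, `slope`, `intercept`).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort_field("y", "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort_field("x", "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_field("x", "correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  res <- tibble(
    r = unname(ct$estimate), p = ct$p.value, n = n,
    r_squared = unname(ct$estimate)^2,
    mse = mean(residuals(fit)^2),
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])
  )
  class(res) <- c("corr_result", class(res))
  res
}

#' Analytic power of the Pearson correlation test
#'
#' Two-sided power at significance level `alpha` for detecting a population
#' correlation `rho` with `n` pairs, via the Fisher z approximation: with
#' effect \eqn{\delta = \mathrm{atanh}(\rho)\sqrt{n-3}}, power is
#' \eqn{\Phi(\delta - z_{1-\alpha/2}) + \Phi(-\delta - z_{1-\alpha/2})}.
#' At `rho = 0` the power equals `alpha` by construction.
#'
#' @param rho Population correlation, |rho| < 1.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1), vectorized over `rho` and `n`.
#' @export
#' @examples
#' pearson_power(0.87, 8)  # ~0.85
pearson_power <- function(rho, n, alpha = 0.05) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    abort_field("rho", "must satisfy |rho| < 1")
  }
  if (any(!is.finite(n)) || any(n < 4)) abort_field("n", "must be >= 4")
  check_scalar_num(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  zc <- qnorm(1 - alpha / 2)
  eff <- atanh(rho) * sqrt(n - 3)
  pnorm(eff - zc) + pnorm(-eff - zc)
}
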