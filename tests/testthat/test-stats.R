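test_that("probe-day t-tests match closed forms and handle degeneracy", {
  d <- tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  res <- day5_tests(d, y, g)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  # unequal n is allowed
  d2 <- tibble(g = c("a", "a", "a", "b", "b"), y = c(1, 2, 3, 4, 5))
  expect_equal(nrow(day5_tests(d2, y, g)), 1L)
  # degenerate zero-variance cases
  dz <- tibble(g = rep(c("a", "b"), each = 2), y = c(1, 1, 1, 1))
  expect_equal(day5_tests(dz, y, g)$p, 1)
  dz2 <- tibble(g = rep(c("a", "b"), each = 2), y = c(1, 1, 2, 2))
  r2 <- day5_tests(dz2, y, g)
  expect_equal(r2$p, 0)
  expect_true(r2$degenerate)
  # Welch variant runs and reports fractional df
  rw <- day5_tests(d, y, g, welch = TRUE)
  expect_lt(abs(rw$t), abs(res$t) + 1e-9)
})

test_that("chance-level test matches the closed-form one-sample t", {
  r <- chance_level_test(c(30, 35, 40), 25)
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  expect_equal(chance_level_test(c(20, 25, 30), 25)$t, 0)
  expect_equal(chance_level_test(c(20, 25, 30), 25)$p, 1)
  expect_error(chance_level_test(30, 25), "n >= 2")
  expect_true(chance_level_test(c(30, 30, 30), 25)$degenerate)
})

test_that("Cohen's d uses the n-1 pooled SD with the stated sign convention", {
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_gt(cohens_d(c(5, 6), c(1, 2)), 0)
  expect_warning(dd <- cohens_d(c(1, 1), c(1, 1)), "zero")
  expect_true(is.na(dd))
})

test_that("pearson_corr reproduces hand-computed values and identities", {
  r <- pearson_corr(1:4, c(2, 1, 4, 3))
  expect_equal(r$r, 0.6)
  expect_equal(r$p, 2 * pt(-0.6 * sqrt(2) / sqrt(1 - 0.36), 2), tolerance = 1e-9)
  expect_equal(r$r_squared, r$r^2)
  perfect <- pearson_corr(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_corr(1:2, 1:2), "pairs")
})

test_that("analytic power behaves like a power function", {
  expect_equal(round(pearson_power(0.87, 8), 2), 0.85)
  expect_equal(pearson_power(0, 30), 0.05, tolerance = 1e-12)
  rhos <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(pearson_power(rhos, 20)) > 0))
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(pearson_power(0.4, ns)) > 0))
  expect_error(pearson_power(1, 10), "rho")
  expect_error(pearson_power(0.5, 3), "n")
})

test_that("mixed-intercepts model recovers known effects and flags degeneracies", {
  # zero-noise cohort: fixed effects reproduce the generating means exactly
  layers <- dplyr::mutate(default_layer_effects(),
                          sd_intercept = 0, sd_eye = 0, sd_resid = 0)
  cc <- cohort_config(n_per_cell = 4, layers = layers, rho = c(tg_f = 0),
                      dropout = NULL, seed = 1)
  coh <- dplyr::mutate(generate_cohort(cc)$cohort, parameter = .data$layer)
  # a zero-noise fit is exactly singular; lme4's scaling chatter is expected
  fit <- suppressWarnings(fit_mixed_intercepts(coh, "TOTAL"))
  cells <- coh |>
    dplyr::filter(.data$layer == "TOTAL") |>
    dplyr::group_by(.data$genotype, .data$sex, .data$week) |>
    dplyr::summarise(mu = mean(.data$value), .groups = "drop")
  pred <- predict(fit$fit, newdata = dplyr::mutate(cells, week_f = factor(week),
                                                   animal = NA),
                  re.form = NA)
  expect_equal(unname(pred), cells$mu, tolerance = 1e-8)
  # single timepoint only, one animal -> precondition error
  single <- dplyr::filter(coh, .data$animal == .data$animal[1])
  expect_error(fit_mixed_intercepts(single, "TOTAL"), "animals")
})

test_that("marginal-means contrasts equal the pooled t-test in the degenerate case", {
  set.seed(4)
  d <- tibble(
    animal = sprintf("a%02d", 1:24),
    genotype = rep(c("tg", "ntg"), each = 12),
    sex = "f", eye = "OD", week = 12, parameter = "INL",
    value = rnorm(24, rep(c(27, 29), each = 12), 1.5)
  )
  fit <- fit_mixed_intercepts(d, "INL")
  expect_true(fit$single_obs_fallback)
  ctr <- pairwise_emmeans(fit)
  tt <- t.test(value ~ genotype, data = d, var.equal = TRUE)
  expect_lt(abs(ctr$p - tt$p.value), 1e-6)
  expect_equal(unname(abs(ctr$estimate)),
               unname(abs(diff(as.numeric(tapply(d$value, d$genotype, mean))))),
               tolerance = 1e-9)
  # identical groups: estimate 0, p ~ 1
  d0 <- d; d0$value <- rep(c(1, 2, 3), 8)
  f0 <- fit_mixed_intercepts(d0, "INL")
  c0 <- pairwise_emmeans(f0)
  expect_equal(c0$estimate, 0, tolerance = 1e-9)
  expect_gt(c0$p, 0.99)
})

test_that("a configured sex difference at the last week is recovered by contrasts", {
  layers <- default_layer_effects() |>
    dplyr::mutate(baseline = ifelse(.data$layer == "TOTAL" & .data$sex == "m",
                                    .data$baseline + 4, .data$baseline))
  cc <- cohort_config(n_per_cell = 40, layers = layers, rho = c(tg_f = 0),
                      dropout = NULL, seed = 6)
  coh <- dplyr::mutate(generate_cohort(cc)$cohort, parameter = .data$layer)
  fit <- fit_mixed_intercepts(dplyr::filter(coh, .data$genotype == "tg"), "TOTAL")
  ctr <- pairwise_emmeans(fit)
  wk36 <- dplyr::filter(ctr, .data$week == "36")
  true_diff <- with(dplyr::filter(default_layer_effects(), layer == "TOTAL",
                                  genotype == "tg"),
                    baseline[sex == "f"] - baseline[sex == "m"]) - 4
  expect_lt(abs(wk36$estimate - true_diff), 2 * wk36$se)
})

test_that("tidy and glance summarize mixed fits", {
  cc <- cohort_config(n_per_cell = 6, rho = c(tg_f = 0), dropout = NULL, seed = 2)
  coh <- dplyr::mutate(generate_cohort(cc)$cohort, parameter = .data$layer)
  fit <- fit_mixed_intercepts(coh, "INL")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(dplyr::filter(coh, .data$layer == "INL")))
  expect_true(gl$var_intercept >= 0)
})

test_that("retina-behavior correlation averages eyes and emits per-group results", {
  retina <- tibble(
    animal = rep(c("m1", "m2", "m3", "m4", "m5", "m6", "m7", "m8"), each = 2),
    genotype = rep(c("tg", "tg", "tg", "ntg", "ntg", "ntg", "ntg", "ntg"), each = 2),
    sex = rep(c("f", "f", "f", "m", "m", "m", "f", "f"), each = 2),
    eye = rep(c("OD", "OS"), 8),
    parameter = "INL",
    value = c(100, 102, 90, 94, 95, 97, 80, 84, 70, 75, 76, 78, 82, 86, 88, 90)
  )
  behavior <- tibble(animal = paste0("m", 1:8),
                     parameter = "crossings", value = c(5, 3, 4, 2, 1, 2, 3, 4))
  out <- correlate_retina_behavior(retina, behavior)
  # eye averaging: correlations are computed on per-mouse means
  tg <- dplyr::filter(out, .data$group == "tg")
  expect_equal(tg$r, cor(c(101, 92, 96), c(5, 3, 4)))
  expect_false(tg$skipped)
  # groups below three complete pairs are skipped with a reason
  skipped <- dplyr::filter(out, .data$group == "ntg_female")
  expect_true(skipped$skipped)
  expect_match(skipped$reason, "n = 2")
})

test_that("the full six-group structure appears with enough animals", {
  cc <- cohort_config(n_per_cell = 6, rho = c(tg_f = 0.6), dropout = NULL, seed = 5)
  g <- generate_cohort(cc)
  retina <- g$cohort |>
    dplyr::filter(.data$week == 36) |>
    dplyr::select("animal", "genotype", "sex", "eye", parameter = "layer", "value")
  behavior <- dplyr::transmute(g$ability, animal = .data$animal,
                               parameter = "ability", value = .data$ability)
  out <- correlate_retina_behavior(retina, behavior)
  expect_setequal(unique(out$group),
                  c("tg", "tg_female", "tg_male", "ntg", "ntg_female", "ntg_male"))
  expect_true(all(out$r_squared[!out$skipped] - out$r[!out$skipped]^2 < 1e-12))
  tmp <- withr::local_tempdir()
  paths <- write_correlation_tables(out, tmp)
  expect_length(paths, 6L)
  expect_true(all(file.exists(paths)))
})
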