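#' Fit the longitudinal mixed-intercepts model
#'
#' Fits a linear mixed model with a random intercept per animal to one
#' retinal parameter from a long-format table, the standard way to account
#' for repeated measurements (timepoints and two eyes) within a mouse.
#' Fixed effects are the full factorial of genotype, sex and week, with week
#' categorical by default (the study compares discrete timepoints); a
#' linear-in-week variant is available via `week_factor = FALSE`. Fitting is
#' by REML through \code{lme4::lmer} and is deterministic given the data.
#'
#' Factors observed at a single level are dropped from the fixed part so
#' degenerate designs (one sex, one week) remain fittable. When every animal
#' contributes exactly one observation the per-animal intercept is not
#' identifiable and the model reduces, exactly, to ordinary least squares;
#' in that case an \code{lm} fit is used and flagged.
#'
#' @param data Long table with columns `animal`, `genotype`, `sex`, `eye`,
#'   `week`, `parameter`, `value` (one row per eye x week x parameter).
#' @param parameter Name of the parameter to model (matched against the
#'   `parameter` column).
#' @param week_factor Treat week as categorical (default) or linear.
#' @return An object of class `mixfit`: the underlying fit, the modelling
#'   frame, variance components and a convergence flag. Methods:
#'   \code{tidy()}, \code{glance()}, \code{pairwise_emmeans()}.
#' @seealso [pairwise_emmeans()]
#' @export
fit_mixed_intercepts <- function(data, parameter, week_factor = TRUE) {
  check_flag(week_factor, "week_factor")
  need <- c("animal", "genotype", "sex", "week", "parameter", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort_field("data", paste("missing columns:", paste(miss, collapse = ", ")))
  d <- dplyr::filter(data, .data$parameter == !!parameter, is.finite(.data$value))
  if (nrow(d) == 0L) abort_field("parameter", sprintf("no rows for parameter '%s'", parameter))
  d <- dplyr::mutate(d,
    animal = factor(.data$animal),
    genotype = factor(.data$genotype),
    sex = factor(.data$sex),
    week_f = if (week_factor) factor(.data$week) else NULL
  )
  n_weeks <- dplyr::n_distinct(d$week)
  n_tp_per_animal <- dplyr::count(d, .data$animal)
  if (nlevels(d$animal) < 2L) abort_field("data", "need >= 2 animals")
  if (week_factor && n_weeks < 1L) abort_field("data", "no timepoints")

  terms <- c(
    if (nlevels(d$genotype) > 1L) "genotype",
    if (nlevels(d$sex) > 1L) "sex",
    if (week_factor && n_weeks > 1L) "week_f"
    else if (!week_factor && n_weeks > 1L) "week"
  )
  fixed <- if (length(terms)) paste(terms, collapse = " * ") else "1"

  single_obs <- nrow(d) == nlevels(d$animal)
  if (single_obs) {
    # random intercept confounded with the residual: the REML solution is OLS
    fit <- lm(as.formula(paste("value ~", fixed)), data = d)
    vc <- c(intercept = 0, residual = summary(fit)$sigma^2)
    converged <- TRUE
  } else {
    form <- as.formula(paste("value ~", fixed, "+ (1 | animal)"))
    fit <- lme4::lmer(form, data = d, REML = TRUE)
    vcs <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(intercept = vcs$vcov[vcs$grp == "animal"],
            residual = vcs$vcov[vcs$grp == "Residual"])
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  }
  structure(
    list(fit = fit, data = d, parameter = parameter,
         week_factor = week_factor, fixed_terms = terms,
         variance = vc, converged = converged,
         single_obs_fallback = single_obs),
    class = "mixfit"
  )
}

#' @export
print.mixfit <- function(x, ...) {
  cat("Mixed-intercepts fit for parameter:", x$parameter, "\n")
  cat(sprintf("  %d observations, %d animals%s\n", nrow(x$data),
              nlevels(x$data$animal),
              if (x$single_obs_fallback) " (OLS fallback: one obs/animal)" else ""))
  cat(sprintf("  random-intercept SD %.3f, residual SD %.3f\n",
              sqrt(x$variance[["intercept"]]), sqrt(x$variance[["residual"]])))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @method tidy mixfit
#' @export
tidy.mixfit <- function(x, ...) {
  cf <- if (inherits(x$fit, "lm")) summary(x$fit)$coefficients
        else coef(summary(x$fit))
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "t value"]
  )
}

#' @method glance mixfit
#' @export
glance.mixfit <- function(x, ...) {
  tibble(
    parameter = x$parameter,
    n_obs = nrow(x$data),
    n_animals = nlevels(x$data$animal),
    var_intercept = unname(x$variance[["intercept"]]),
    var_residual = unname(x$variance[["residual"]]),
    converged = x$converged
  )
}

#' Pairwise comparisons from estimated marginal means
#'
#' Computes marginal means for each group cell of a [fit_mixed_intercepts()]
#' model and all pairwise contrasts between them, optionally within each
#' week. P-values use the t-distribution on residual degrees of freedom
#' (observations minus fixed-effect parameters) applied to the contrast SE
#' from the marginal-means machinery; no multiplicity correction is applied,
#' matching the exploratory design (a Benjamini-Hochberg adjustment can be
#' requested with `adjust = "BH"`).
#'
#' In the balanced single-week two-group case with zero random-intercept
#' variance this reduces exactly to the classical pooled two-sample t-test.
#'
#' @param fit A `mixfit` object with `converged = TRUE`.
#' @param by Condition contrasts on this factor (default `"week_f"` when
#'   week is categorical and in the model, otherwise none).
#' @param adjust Multiplicity adjustment passed to emmeans (default "none").
#' @return A tibble of contrasts: `contrast`, optional `week`, `estimate`,
#'   `se`, `df`, `t`, `p`.
#' @export
pairwise_emmeans <- function(fit, by = NULL, adjust = "none") {
  if (!inherits(fit, "mixfit")) abort_field("fit", "must be a mixfit object")
  if (!fit$converged) {
    stop("mixed-model fit did not converge; contrasts suppressed", call. = FALSE)
  }
  grp_terms <- intersect(c("genotype", "sex"), fit$fixed_terms)
  if (is.null(by)) by <- if ("week_f" %in% fit$fixed_terms) "week_f" else NULL
  if (!length(grp_terms)) {
    # no group factors: contrast weeks instead
    grp_terms <- "week_f"
    by <- NULL
    if (!"week_f" %in% fit$fixed_terms) abort_field("fit", "no factors to contrast")
  }
  specs <- as.formula(paste("~", paste(c(grp_terms, by), collapse = " + ")))
  df_resid <- nrow(fit$data) - length(coef_count(fit))
  emm <- emmeans::emmeans(fit$fit, specs = specs,
                          lmer.df = "asymptotic",
                          data = fit$data)
  ctr <- emmeans::contrast(emm, method = "pairwise", by = by, adjust = adjust)
  s <- as.data.frame(summary(ctr, infer = FALSE))
  tstat <- s$estimate / s$SE
  out <- tibble(
    contrast = as.character(s$contrast),
    estimate = s$estimate,
    se = s$SE,
    df = df_resid,
    t = tstat,
    p = 2 * pt(-abs(tstat), df_resid)
  )
  if (!is.null(by) && by %in% names(s)) {
    out <- dplyr::mutate(out, week = as.character(s[[by]]), .after = "contrast")
  }
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out
}

coef_count <- function(fit) {
  if (inherits(fit$fit, "lm")) coef(fit$fit) else lme4::fixef(fit$fit)
}
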