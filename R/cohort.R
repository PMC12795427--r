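#' Configuration for the longitudinal cohort generator
#'
#' Describes a synthetic longitudinal study: group sizes per genotype x sex
#' cell, imaging timepoints, per-layer baselines and variance components of
#' a random-intercepts model, group time slopes, a latent spatial-memory
#' ability per animal, a configurable correlation between final-timepoint
#' inner-nuclear-layer (INL) thickness and that ability, and a dropout
#' schedule. Defaults mirror a 6-month study design: 16 animals per
#' genotype x sex cell (64 total), timepoints at 12/20/24/36 weeks, and
#' staged removals (16 animals after week 12, 21 after week 24) leaving 27
#' animals at week 36.
#'
#' @param n_per_cell Animals per genotype x sex cell (recycled over the 4
#'   cells tg/ntg x f/m, or a named vector like `c(tg_f = 16, ...)`).
#' @param timepoints Strictly increasing imaging weeks.
#' @param layers Tibble of generating effects with columns `layer`,
#'   `genotype`, `sex`, `baseline` (um at the first timepoint), `slope`
#'   (um/week), `sd_intercept`, `sd_eye`, `sd_resid` (um). Defaults via
#'   [default_layer_effects()].
#' @param rho Named numeric: target correlation between eye-averaged INL
#'   thickness at the final timepoint and latent memory ability, per group
#'   (`"tg_f"` etc.); groups not named get 0.
#' @param rho_layer Layer carrying the correlation (default "INL").
#' @param dropout Tibble with columns `after_week`, `genotype`, `n_remove`:
#'   that many animals of that genotype are removed from all weeks after
#'   `after_week`. Default reproduces 64 -> 48 -> 48 -> 27.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_per_cell = 16,
                          timepoints = c(12, 20, 24, 36),
                          layers = default_layer_effects(),
                          rho = c(tg_f = 0.87),
                          rho_layer = "INL",
                          dropout = default_dropout(),
                          seed = 1L) {
  cells <- c("tg_f", "tg_m", "ntg_f", "ntg_m")
  if (is.null(names(n_per_cell))) {
    n_per_cell <- setNames(rep_len(n_per_cell, 4L), cells)
  }
  if (any(n_per_cell < 0)) abort_field("n_per_cell", "must be >= 0")
  if (length(timepoints) < 1L || is.unsorted(timepoints, strictly = TRUE)) {
    abort_field("timepoints", "must be strictly increasing")
  }
  need <- c("layer", "genotype", "sex", "baseline", "slope",
            "sd_intercept", "sd_eye", "sd_resid")
  if (length(setdiff(need, names(layers)))) {
    abort_field("layers", paste("needs columns", paste(need, collapse = ", ")))
  }
  if (any(layers$sd_intercept < 0 | layers$sd_eye < 0 | layers$sd_resid < 0)) {
    abort_field("layers", "all SDs must be >= 0")
  }
  if (any(abs(rho) > 1)) abort_field("rho", "|rho| must be <= 1")
  rho_full <- setNames(rep(0, 4L), cells)
  rho_full[names(rho)] <- rho
  if (!is.null(dropout) && nrow(dropout) &&
      length(setdiff(c("after_week", "genotype", "n_remove"), names(dropout)))) {
    abort_field("dropout", "needs columns after_week, genotype, n_remove")
  }
  structure(
    list(n_per_cell = n_per_cell, timepoints = timepoints, layers = layers,
         rho = rho_full, rho_layer = rho_layer, dropout = dropout,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default per-layer generating effects
#'
#' Plausible murine retinal layer baselines (um) with small sex and genotype
#' offsets and mild thickening over time, and variance components sized so
#' the default INL-memory correlation of 0.87 is attainable through the
#' animal-level intercept.
#'
#' @return Tibble usable as the `layers` argument of [cohort_config()].
#' @export
default_layer_effects <- function() {
  base <- tibble(
    layer = c("TOTAL", "IRL", "ORL", "RNFL_GCL", "IPL", "INL", "OPL", "PRC", "RPE"),
    baseline = c(221, 95, 126, 42, 26, 27, 18, 80, 28),
    slope = c(0.24, 0.05, 0.16, 0.02, 0.02, 0.01, 0.02, 0.1, 0.04),
    sd_intercept = c(6, 3.5, 4, 2.5, 2, 2, 1.5, 3, 1.5),
    sd_eye = c(2, 1.2, 1.5, 1, 0.8, 0.8, 0.7, 1.2, 0.6),
    sd_resid = c(2.5, 1.5, 1.8, 1.2, 1, 1, 0.9, 1.4, 0.8)
  )
  grid <- tidyr::expand_grid(genotype = c("tg", "ntg"), sex = c("f", "m"))
  out <- tidyr::crossing(base, grid)
  # males run a few um thicker in the inner retina; genotype effect small
  dplyr::mutate(out,
    baseline = .data$baseline +
      ifelse(.data$sex == "m" & .data$layer %in% c("TOTAL", "IRL", "RNFL_GCL", "IPL", "INL"),
             c(TOTAL = 4, IRL = 2.5, RNFL_GCL = 1, IPL = 0.8, INL = 0.7)[.data$layer], 0) +
      ifelse(.data$genotype == "tg" & .data$layer %in% c("TOTAL", "IRL"),
             0.5, 0)
  )
}

#' @rdname cohort_config
#' @export
default_dropout <- function() {
  tibble(
    after_week = c(12, 12, 24, 24),
    genotype = c("tg", "ntg", "tg", "ntg"),
    n_remove = c(8L, 8L, 10L, 11L)
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a long-format cohort table from a random-intercepts model: for each
#' layer and group, value = baseline + slope x (week - first week) + animal
#' intercept + eye offset + residual. Each animal also carries a latent
#' memory ability (standard normal); for the configured layer the animal
#' intercept is constructed from that ability so that the eye-averaged
#' thickness at the final timepoint has the configured population
#' correlation with ability, per group. Dropout removes animals from weeks
#' after the configured cut.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (tibble: animal, genotype, sex, eye, week,
#'   layer, parameter-value column `value`, plus a `clipped` flag for values
#'   truncated at zero) and `ability` (tibble: animal, genotype, sex,
#'   ability).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_field("config", "must be a cohort_config")
  }
  withr_seed <- set_local_seed(config$seed)
  on.exit(withr_seed(), add = TRUE)

  cells <- tibble(
    cell = names(config$n_per_cell),
    genotype = sub("_.*$", "", names(config$n_per_cell)),
    sex = sub("^.*_", "", names(config$n_per_cell)),
    n = as.integer(config$n_per_cell)
  )
  animals <- cells |>
    dplyr::filter(.data$n > 0L) |>
    purrr::pmap(function(cell, genotype, sex, n) {
      tibble(cell = cell, genotype = genotype, sex = sex, idx = seq_len(n))
    }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(animal = sprintf("%s_%02d", .data$cell, .data$idx))
  animals$ability <- rnorm(nrow(animals))

  wk0 <- config$timepoints[1]
  wk_last <- config$timepoints[length(config$timepoints)]
  eyes <- c("OD", "OS")

  rows <- purrr::pmap(config$layers, function(layer, genotype, sex, baseline,
                                              slope, sd_intercept, sd_eye,
                                              sd_resid, ...) {
    an <- dplyr::filter(animals, .data$genotype == !!genotype, .data$sex == !!sex)
    if (nrow(an) == 0L) return(NULL)
    rho <- config$rho[[paste(genotype, sex, sep = "_")]]
    b <- draw_intercepts(an$ability, rho, layer == config$rho_layer,
                         sd_intercept, sd_eye, sd_resid)
    e <- matrix(rnorm(nrow(an) * 2L, sd = sd_eye), ncol = 2L)
    grid <- tidyr::expand_grid(i = seq_len(nrow(an)),
                               week = config$timepoints, eye = eyes)
    mu <- baseline + slope * (grid$week - wk0)
    resid <- rnorm(nrow(grid), sd = sd_resid)
    tibble(
      animal = an$animal[grid$i], genotype = genotype, sex = sex,
      eye = grid$eye, week = grid$week, layer = layer,
      value = mu + b[grid$i] + e[cbind(grid$i, match(grid$eye, eyes))] + resid
    )
  }) |> dplyr::bind_rows()

  rows <- dplyr::mutate(rows,
    clipped = .data$value < 0,
    value = pmax(.data$value, 0)
  )
  if (any(rows$clipped)) {
    warning(sprintf("%d generated thicknesses clipped at 0", sum(rows$clipped)))
  }

  # dropout: remove whole animals from all weeks strictly after the cut
  if (!is.null(config$dropout) && nrow(config$dropout)) {
    for (k in seq_len(nrow(config$dropout))) {
      dk <- config$dropout[k, ]
      pool <- animals$animal[animals$genotype == dk$genotype]
      already <- attr(rows, "dropped") %||% character()
      pool <- setdiff(pool, already)
      gone <- sample(pool, min(dk$n_remove, length(pool)))
      rows <- dplyr::filter(rows,
        !(.data$animal %in% gone & .data$week > dk$after_week))
      attr(rows, "dropped") <- c(already, gone)
    }
  }

  list(
    cohort = rows,
    ability = dplyr::select(animals, "animal", "genotype", "sex", "ability")
  )
}

# Animal intercepts; for the correlation-carrying layer they share a latent
# factor with ability such that the eye-averaged value at the final week has
# population correlation rho with ability.
draw_intercepts <- function(ability, rho, is_rho_layer, sd_b, sd_eye, sd_resid) {
  n <- length(ability)
  if (!is_rho_layer || rho == 0 || sd_b == 0) return(rnorm(n, sd = sd_b))
  var_final <- sd_b^2 + (sd_eye^2 + sd_resid^2) / 2
  lambda <- rho * sqrt(var_final)
  if (abs(lambda) > sd_b) {
    abort_field("rho", sprintf(
      "target correlation %.2f unattainable: needs |loading| %.2f > sd_intercept %.2f",
      rho, abs(lambda), sd_b))
  }
  lambda * ability + rnorm(n, sd = sqrt(sd_b^2 - lambda^2))
}

# set.seed scoped to the caller: returns a restore function
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
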