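#' Correlate retinal parameters with behavioral metrics
#'
#' Orchestrates the structure-function correlation analysis: retinal
#' parameters (per eye) are averaged over the two eyes of each mouse so that
#' each animal enters as one statistical unit, joined to per-animal
#' behavioral metrics, and Pearson-correlated per analysis group. The six
#' standard groupings are all transgenic animals, transgenic females,
#' transgenic males, and the same three for non-transgenic animals.
#'
#' @param retina Long table with columns `animal`, `genotype`, `sex`, `eye`,
#'   `parameter`, `value` (already restricted to the timepoint of interest;
#'   body weight may be included as just another parameter row).
#' @param behavior Long table with columns `animal`, `parameter`, `value`
#'   (one row per animal and behavioral metric).
#' @param groupings Optional named list of filter functions
#'   `function(genotype, sex) -> logical`; defaults to the six standard
#'   groups.
#' @param min_n Minimum complete pairs per correlation (default 3); smaller
#'   groups are reported with `skipped = TRUE` and a reason.
#' @return A tibble with one row per (group, retinal parameter, behavioral
#'   parameter): correlation `r`, `p`, `n`, `r_squared`, `mse`, `slope`,
#'   `intercept`, plus `skipped`/`reason`.
#' @export
correlate_retina_behavior <- function(retina, behavior, groupings = NULL,
                                      min_n = 3L) {
  need_r <- c("animal", "genotype", "sex", "parameter", "value")
  if (length(setdiff(need_r, names(retina)))) {
    abort_field("retina", paste("needs columns", paste(need_r, collapse = ", ")))
  }
  need_b <- c("animal", "parameter", "value")
  if (length(setdiff(need_b, names(behavior)))) {
    abort_field("behavior", paste("needs columns", paste(need_b, collapse = ", ")))
  }
  if (is.null(groupings)) groupings <- standard_groupings()
  min_n <- max(as.integer(min_n), 3L) # a p-value needs at least 3 pairs

  # one datapoint per mouse: average available eyes
  per_mouse <- retina |>
    dplyr::group_by(.data$animal, .data$genotype, .data$sex, .data$parameter) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")

  purrr::imap(groupings, function(keep, gname) {
    sub <- dplyr::filter(per_mouse, keep(.data$genotype, .data$sex))
    if (nrow(sub) == 0L) return(NULL)
    grid <- tidyr::expand_grid(
      retina_parameter = unique(sub$parameter),
      behavior_parameter = unique(behavior$parameter)
    )
    purrr::pmap(grid, function(retina_parameter, behavior_parameter) {
      rp <- dplyr::filter(sub, .data$parameter == retina_parameter)
      bp <- dplyr::filter(behavior, .data$parameter == behavior_parameter)
      j <- dplyr::inner_join(
        dplyr::select(rp, "animal", retina = "value"),
        dplyr::select(bp, "animal", behavior = "value"),
        by = "animal"
      )
      j <- dplyr::filter(j, is.finite(.data$retina), is.finite(.data$behavior))
      base <- tibble(group = gname,
                     retina_parameter = retina_parameter,
                     behavior_parameter = behavior_parameter)
      if (nrow(j) < min_n) {
        return(dplyr::mutate(base, n = nrow(j), r = NA_real_, p = NA_real_,
                             r_squared = NA_real_, mse = NA_real_,
                             slope = NA_real_, intercept = NA_real_,
                             skipped = TRUE,
                             reason = sprintf("n = %d < %d", nrow(j), min_n)))
      }
      if (sd(j$retina) == 0 || sd(j$behavior) == 0) {
        return(dplyr::mutate(base, n = nrow(j), r = NA_real_, p = NA_real_,
                             r_squared = NA_real_, mse = NA_real_,
                             slope = NA_real_, intercept = NA_real_,
                             skipped = TRUE, reason = "constant input"))
      }
      cr <- pearson_corr(j$retina, j$behavior)
      dplyr::bind_cols(base,
        tibble(n = cr$n, r = cr$r, p = cr$p, r_squared = cr$r_squared,
               mse = cr$mse, slope = cr$slope, intercept = cr$intercept,
               skipped = FALSE, reason = NA_character_))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

standard_groupings <- function() {
  list(
    tg         = function(g, s) g == "tg",
    tg_female  = function(g, s) g == "tg" & s == "f",
    tg_male    = function(g, s) g == "tg" & s == "m",
    ntg        = function(g, s) g == "ntg",
    ntg_female = function(g, s) g == "ntg" & s == "f",
    ntg_male   = function(g, s) g == "ntg" & s == "m"
  )
}

#' Write per-group correlation tables
#'
#' Writes the output of [correlate_retina_behavior()] as one CSV per group.
#'
#' @param corr Tibble from [correlate_retina_behavior()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_correlation_tables <- function(corr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(unique(corr$group), function(g) {
    p <- file.path(dir, paste0("correlations_", g, ".csv"))
    readr::write_csv(dplyr::filter(corr, .data$group == g), p)
    p
  })
  invisible(paths)
}
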