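# On-disk interfaces: multi-page TIFF for volumes and en-face maps, CSV for
# tables and trajectories, YAML sidecars for pool geometry.

#' Write / read an OCT volume as multi-page TIFF
#'
#' Pages are depth slices (32-bit float), repeats concatenated; intensity
#' and depolarization go to separate files. Spacings travel in a YAML
#' sidecar next to the TIFF.
#'
#' @param vol An [oct_volume()].
#' @param path Output TIFF path (sidecar written as `<path>.meta.yaml`).
#' @return Invisibly, `path`.
#' @export
write_volume_tiff <- function(vol, path) {
  if (!inherits(vol, "oct_volume")) abort_field("vol", "must be an oct_volume")
  d <- dim(vol$intensity)
  pages <- list()
  for (r in seq_len(d[4])) {
    for (j in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- vol$intensity[, , j, r] / max(vol$intensity)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(nz = d[1], nx = d[2], ny = d[3], n_repeats = d[4],
               dx_um = vol$dx_um, dy_um = vol$dy_um, dz_um = vol$dz_um,
               scale = max(vol$intensity))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  if (!is.null(vol$depol)) {
    dep_pages <- purrr::map(seq_len(d[3]), ~ vol$depol[, , .x])
    tiff::writeTIFF(dep_pages, sub("\\.tiff?$", "_depol.tif", path),
                    bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(meta$nz, meta$nx, meta$ny, meta$n_repeats))
  k <- 1L
  for (r in seq_len(meta$n_repeats)) {
    for (j in seq_len(meta$ny)) {
      arr[, , j, r] <- pages[[k]] * meta$scale
      k <- k + 1L
    }
  }
  dep_path <- sub("\\.tiff?$", "_depol.tif", path)
  depol <- NULL
  if (file.exists(dep_path)) {
    dp <- tiff::readTIFF(dep_path, all = TRUE)
    depol <- array(0, dim = c(meta$nz, meta$nx, meta$ny))
    for (j in seq_len(meta$ny)) depol[, , j] <- dp[[j]]
  }
  oct_volume(arr, depol, meta$dx_um, meta$dy_um, meta$dz_um)
}

#' Write an en-face thickness map as 32-bit float TIFF (micrometres)
#'
#' @param map A `thickness_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_thickness_tiff <- function(map, path) {
  if (!inherits(map, "thickness_map")) abort_field("map", "must be a thickness_map")
  tiff::writeTIFF(map$values / 1000, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write / read a swim trajectory as CSV with a YAML pool sidecar
#'
#' Columns `t_s`, `x_m`, `y_m`; the pool geometry is stored next to the
#' trajectory as `<path>.pool.yaml` so a trajectory file is self-contained.
#'
#' @param traj Trajectory tibble.
#' @param geom A [pool_geometry()].
#' @param path CSV path.
#' @return Invisibly, `path`; `read_trajectory_csv` returns a list
#'   `(trajectory, geom)`.
#' @export
write_trajectory_csv <- function(traj, geom, path) {
  readr::write_csv(traj[, c("t_s", "x_m", "y_m")], path)
  yaml::write_yaml(list(
    pool_radius = geom$pool_radius,
    platform_quadrant = geom$platform_quadrant,
    platform_radius = geom$platform_radius,
    platform_dist = sqrt(sum(geom$platform_center^2)),
    wall_width = geom$wall_width
  ), paste0(path, ".pool.yaml"))
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  gy <- yaml::read_yaml(paste0(path, ".pool.yaml"))
  geom <- pool_geometry(
    pool_radius = gy$pool_radius, platform_quadrant = gy$platform_quadrant,
    platform_radius = gy$platform_radius, platform_dist = gy$platform_dist,
    wall_width = gy$wall_width
  )
  list(trajectory = traj, geom = geom)
}

#' Write / read a cohort table as CSV
#'
#' Long format: `animal`, `genotype`, `sex`, `eye`, `week`, `layer`,
#' `thickness_um`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param path CSV path.
#' @return Invisibly, `path`; the reader returns the tibble with the
#'   internal `value` column restored.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- dplyr::select(cohort, "animal", "genotype", "sex", "eye", "week",
                       "layer", thickness_um = "value")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::rename(x, value = "thickness_um")
}
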