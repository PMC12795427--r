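# Shared fixtures: small phantoms and deterministic trajectories so unit
# tests stay fast; acceptance-scale runs live in test-acceptance.R.

tiny_dims <- c(96L, 80L, 224L)

tiny_phantom_config <- function(...) {
  args <- list(...)
  defaults <- list(dims = tiny_dims, ilm_depth_um = 60, seed = 1L)
  do.call(phantom_config, utils::modifyList(defaults, args))
}

noise_free_config <- function(...) {
  tiny_phantom_config(
    noise_floor = 0, speckle = FALSE,
    vessel_density = c(SVP = 0, ICP = 0, DCP = 0), ...
  )
}

flat_plane_config <- function(...) {
  # all surfaces are constant planes: no variation, no tilt, no ONH pit
  noise_free_config(variation_rel = 0, surface_amp_um = 0,
                    onh_radius_um = 0, ...)
}

# straight-line sampled trajectory builder
line_trajectory <- function(from, to, speed, fps = 14) {
  d <- sqrt(sum((to - from)^2))
  n <- max(2L, ceiling(d / speed * fps) + 1L)
  t <- (seq_len(n) - 1) / fps
  f <- pmin(t * speed / d, 1)
  tibble::tibble(t_s = t, x_m = from[1] + f * (to[1] - from[1]),
                 y_m = from[2] + f * (to[2] - from[2]))
}

circle_trajectory <- function(r, revolutions, speed, fps = 14,
                              center = c(0, 0), phase = 0) {
  t_total <- 2 * pi * r * revolutions / speed
  n <- ceiling(t_total * fps) + 1L
  t <- (seq_len(n) - 1) / fps
  th <- phase + speed * t / r
  tibble::tibble(t_s = t, x_m = center[1] + r * cos(th),
                 y_m = center[2] + r * sin(th))
}

# boundary error (axial pixels) between segmented surfaces and phantom
# truth mapped into the flattened frame, outside an exclusion radius
boundary_errors_px <- function(surfaces, truth, flat, cfg, r_excl = 150) {
  nx <- cfg$dims[1]; ny <- cfg$dims[2]
  co <- list(x = (seq_len(nx) - 0.5) * (cfg$fov_um[1] / nx),
             y = (seq_len(ny) - 0.5) * (cfg$fov_um[2] / ny))
  dist <- sqrt(outer((co$x - cfg$onh_center_um[1])^2, rep(1, ny)) +
                 outer(rep(1, nx), (co$y - cfg$onh_center_um[2])^2))
  ok <- dist > r_excl
  sapply(names(truth$boundaries), function(b) {
    err <- abs(surfaces$boundaries[[b]] -
                 (truth$boundaries[[b]] + flat$shift_um)) / cfg$dz_um
    c(mean = mean(err[ok]), max = max(err[ok]))
  })
}
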