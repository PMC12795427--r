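#' Configuration for the layered retinal phantom
#'
#' Describes a synthetic OCT volume of a mouse retina centered on the optic
#' nerve head (ONH): six anatomical layers (RNFL/GCL complex, IPL, INL,
#' OPL, photoreceptor complex, RPE) stacked below the inner limiting
#' membrane with smooth spatial thickness variation, a pit and
#' depolarization gap at the ONH, per-plexus vessel networks of known area
#' density, multiplicative speckle with repeat decorrelation inside
#' vessels, an additive noise floor, and an optional radial signal falloff
#' for SNR-gating tests. The default grid is 256 x 200 x 384 voxels over a
#' 1 x 1 mm field at 1.5 um axial sampling (a desk-scale stand-in for the
#' full 512 x 400 acquisition geometry); full-size generation is supported
#' by passing larger dims.
#'
#' @param dims Integer vector `c(nx, ny, nz)`: fast axis, slow axis, depth.
#' @param n_repeats Repeated B-scans per slow position (>= 1).
#' @param fov_um Lateral field of view `c(x, y)` in micrometres.
#' @param dz_um Axial spacing, micrometres per pixel.
#' @param ilm_depth_um Mean depth of the inner limiting membrane.
#' @param layers Tibble with columns `layer`, `mean_um`, `reflectivity`
#'   for the six layers, in anatomical order.
#' @param variation_rel Relative amplitude of the smooth per-layer
#'   thickness variation (fraction of the layer mean).
#' @param surface_amp_um Amplitude of the smooth ILM surface undulation.
#' @param tilt_um Max additional planar tilt of the ILM across the field
#'   `c(x, y)`.
#' @param onh_center_um ONH center in micrometres (default field center).
#' @param onh_radius_um ONH pit radius.
#' @param vessel_density Named target area densities (fractions) per plexus
#'   `c(SVP = , ICP = , DCP = )`.
#' @param vessel_radius_um Range `c(min, max)` of vessel tube radii.
#' @param vessel_segment_um Maximum length of one vessel segment; shorter
#'   segments give a finer-grained, spatially homogeneous mesh.
#' @param reflectivity_vitreous,reflectivity_below,reflectivity_vessel
#'   Reflectivities outside the layer stack and inside vessels.
#' @param noise_floor Additive noise level (intensity units; 0 disables).
#' @param snr_edge Radial signal multiplier at the farthest field corner
#'   (1 = uniform signal; < 1 creates radially decaying SNR).
#' @param decorr_level Repeat decorrelation inside vessels in [0, 1].
#' @param speckle Draw multiplicative speckle (TRUE) or a deterministic
#'   noise-free structure (FALSE).
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(dims = c(256L, 200L, 384L),
                           n_repeats = 5L,
                           fov_um = c(1000, 1000),
                           dz_um = 1.5,
                           ilm_depth_um = 120,
                           layers = default_phantom_layers(),
                           variation_rel = 0.06,
                           surface_amp_um = 8,
                           tilt_um = c(0, 0),
                           onh_center_um = fov_um / 2,
                           onh_radius_um = 100,
                           vessel_density = c(SVP = 0.20, ICP = 0.15, DCP = 0.15),
                           vessel_radius_um = c(5, 8),
                           vessel_segment_um = 150,
                           reflectivity_vitreous = 0,
                           reflectivity_below = 0.08,
                           reflectivity_vessel = 0.5,
                           noise_floor = 0.002,
                           snr_edge = 1,
                           decorr_level = 0.9,
                           speckle = TRUE,
                           seed = 1L) {
  if (length(dims) != 3L || any(dims < 8)) abort_field("dims", "need 3 dims >= 8")
  check_scalar_num(n_repeats, "n_repeats", lower = 1)
  check_scalar_num(dz_um, "dz_um", lower = 1e-6)
  if (any(fov_um <= 0)) abort_field("fov_um", "must be positive")
  need <- c("layer", "mean_um", "reflectivity")
  if (length(setdiff(need, names(layers))) || nrow(layers) != 6L) {
    abort_field("layers", "need 6 rows with columns layer, mean_um, reflectivity")
  }
  if (any(layers$mean_um <= 0)) abort_field("layers", "layer thicknesses must be > 0")
  if (any(vessel_density < 0 | vessel_density > 1)) {
    abort_field("vessel_density", "densities must be in [0, 1]")
  }
  if (is.null(names(vessel_density)) ||
      !all(names(vessel_density) %in% c("SVP", "ICP", "DCP"))) {
    abort_field("vessel_density", "must be named with SVP/ICP/DCP")
  }
  vd <- c(SVP = 0, ICP = 0, DCP = 0)
  vd[names(vessel_density)] <- vessel_density
  vessel_density <- vd
  if (any(onh_center_um < 0) || any(onh_center_um > fov_um)) {
    abort_field("onh_center_um", "ONH must lie inside the field of view")
  }
  check_scalar_num(onh_radius_um, "onh_radius_um", lower = 0)
  check_scalar_num(variation_rel, "variation_rel", lower = 0, upper = 1)
  check_scalar_num(noise_floor, "noise_floor", lower = 0)
  check_scalar_num(snr_edge, "snr_edge", lower = 1e-6, upper = 1)
  check_scalar_num(decorr_level, "decorr_level", lower = 0, upper = 1)
  check_flag(speckle, "speckle")
  depth_um <- dims[3] * dz_um
  if (ilm_depth_um + sum(layers$mean_um) * (1 + variation_rel) +
      surface_amp_um + sum(abs(tilt_um)) + 10 * dz_um >= depth_um) {
    abort_field("layers",
      "sum of layer thicknesses plus surface variation exceeds the depth extent")
  }
  structure(
    list(dims = as.integer(dims), n_repeats = as.integer(n_repeats),
         fov_um = fov_um, dz_um = dz_um, ilm_depth_um = ilm_depth_um,
         layers = layers, variation_rel = variation_rel,
         surface_amp_um = surface_amp_um, tilt_um = tilt_um,
         onh_center_um = onh_center_um, onh_radius_um = onh_radius_um,
         vessel_density = vessel_density, vessel_radius_um = vessel_radius_um,
         vessel_segment_um = vessel_segment_um,
         reflectivity_vitreous = reflectivity_vitreous,
         reflectivity_below = reflectivity_below,
         reflectivity_vessel = reflectivity_vessel,
         noise_floor = noise_floor, snr_edge = snr_edge,
         decorr_level = decorr_level, speckle = speckle,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Default phantom layer stack
#'
#' Murine layer means (um) and relative reflectivities. Plexiform layers
#' and the RNFL/RPE are bright, nuclear layers dark, giving the alternating
#' gradient signs a boundary search relies on.
#'
#' @return Tibble with columns `layer`, `mean_um`, `reflectivity`.
#' @export
default_phantom_layers <- function() {
  tibble(
    layer = c("RNFL_GCL", "IPL", "INL", "OPL", "PRC", "RPE"),
    mean_um = c(42, 26, 27, 18, 80, 28),
    reflectivity = c(1.0, 0.55, 0.25, 0.6, 0.3, 1.2)
  )
}

boundary_names <- function() {
  c("ILM", "RNFL_GCL_IPL", "IPL_INL", "INL_OPL", "OPL_PRC", "PRC_RPE", "RPE_POST")
}

#' OCT volume container
#'
#' Bundles a reconstructed intensity volume (depth x fast x slow x repeats)
#' with an optional depolarization channel (depth x fast x slow, values in
#' [0, 1]) and the physical pixel spacings.
#'
#' @param intensity 4-D numeric array `[nz, nx, ny, n_repeats]`.
#' @param depol Optional 3-D array `[nz, nx, ny]`.
#' @param dx_um,dy_um,dz_um Pixel spacings in micrometres.
#' @return An `oct_volume` list.
#' @export
oct_volume <- function(intensity, depol = NULL, dx_um, dy_um, dz_um) {
  if (length(dim(intensity)) != 4L) {
    abort_field("intensity", "must be a 4-D array [nz, nx, ny, repeats]")
  }
  for (sp in c(dx_um, dy_um, dz_um)) check_scalar_num(sp, "spacing", lower = 1e-9)
  if (!is.null(depol)) {
    if (!identical(dim(depol), dim(intensity)[1:3])) {
      abort_field("depol", "must share [nz, nx, ny] dims with intensity")
    }
    if (min(depol) < 0 || max(depol) > 1) {
      abort_field("depol", "values must be in [0, 1]")
    }
  }
  structure(
    list(intensity = intensity, depol = depol,
         dx_um = dx_um, dy_um = dy_um, dz_um = dz_um,
         n_repeats = dim(intensity)[4]),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("OCT volume: %d x %d A-scans, %d depth px, %d repeats\n",
              d[2], d[3], d[1], d[4]))
  cat(sprintf("  spacings: %.2f x %.2f x %.2f um/px, depol channel: %s\n",
              x$dx_um, x$dy_um, x$dz_um, if (is.null(x$depol)) "no" else "yes"))
  invisible(x)
}

#' Generate a retinal phantom volume with ground truth
#'
#' Renders the phantom described by a [phantom_config()]: layered
#' reflectivity with smooth boundary surfaces and an ONH pit, vessels drawn
#' as smoothed random-walk tubes within each plexus slab until the target
#' area density is met, multiplicative exponential speckle shared across
#' repeats outside vessels and partially decorrelated inside them, an
#' additive noise floor, and a depolarization channel marking the RPE band
#' (with a gap at the ONH). Identical seeds give identical output.
#'
#' @param config A [phantom_config()].
#' @return A list with `volume` (an [oct_volume()]) and `truth`
#'   (`phantom_truth`: boundary depth maps in um on the en-face grid,
#'   per-plexus vessel masks, realized densities, ONH center).
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) {
    abort_field("config", "must be a phantom_config")
  }
  restore <- set_local_seed(config$seed)
  on.exit(restore(), add = TRUE)

  nx <- config$dims[1]; ny <- config$dims[2]; nz <- config$dims[3]
  dx <- config$fov_um[1] / nx
  dy <- config$fov_um[2] / ny
  dz <- config$dz_um
  co <- enface_coords(nx, ny, dx, dy)

  # --- boundary surfaces -------------------------------------------------
  ilm <- config$ilm_depth_um +
    smooth_field(nx, ny, config$surface_amp_um) +
    outer(co$x / config$fov_um[1], rep(1, ny)) * config$tilt_um[1] +
    outer(rep(1, nx), co$y / config$fov_um[2]) * config$tilt_um[2]
  thick <- purrr::map(seq_len(6), function(l) {
    m <- config$layers$mean_um[l]
    pmax(m * 0.02, m + smooth_field(nx, ny, config$variation_rel * m))
  })
  # ONH pit: all layers pinch smoothly to 2% of their mean inside the disc
  dist_onh <- sqrt(outer((co$x - config$onh_center_um[1])^2,
                         rep(1, ny)) +
                   outer(rep(1, nx), (co$y - config$onh_center_um[2])^2))
  if (config$onh_radius_um > 0) {
    u <- pmin(dist_onh / config$onh_radius_um, 1)
    taper <- 0.02 + 0.98 * (3 * u^2 - 2 * u^3) # smoothstep
    thick <- purrr::map(thick, function(tm) tm * taper)
  }
  bnd <- vector("list", 7L)
  bnd[[1]] <- ilm
  for (l in seq_len(6)) bnd[[l + 1]] <- bnd[[l]] + thick[[l]]
  names(bnd) <- boundary_names()

  # --- vessels ------------------------------------------------------------
  plexus_band <- list(
    SVP = (bnd$ILM + bnd$RNFL_GCL_IPL) / 2,
    ICP = (bnd$RNFL_GCL_IPL + bnd$INL_OPL) / 2,
    DCP = (bnd$INL_OPL + bnd$OPL_PRC) / 2
  )
  vmask <- purrr::imap(plexus_band, function(center, px) {
    target <- unname(config$vessel_density[px] %||% 0)
    draw_vessel_mask(nx, ny, dx, dy, target, config$vessel_radius_um,
                     config$vessel_segment_um %||% 150)
  })
  densities <- purrr::map_dbl(vmask, mean)
  for (px in names(densities)) {
    tgt <- unname(config$vessel_density[px] %||% 0)
    if (abs(densities[[px]] - tgt) > 0.02) {
      stop(sprintf("realized %s density %.3f misses target %.3f", px,
                   densities[[px]], tgt), call. = FALSE)
    }
  }

  # --- deterministic reflectivity volume ----------------------------------
  zc <- (seq_len(nz) - 0.5) * dz
  refl <- config$layers$reflectivity
  r_edge <- max(sqrt(outer((c(0, config$fov_um[1]) - config$onh_center_um[1])^2,
                           rep(1, 2)) +
                     outer(rep(1, 2), (c(0, config$fov_um[2]) - config$onh_center_um[2])^2)))
  snr_mult <- 1 - (1 - config$snr_edge) * (dist_onh / r_edge)^2

  vr_mid <- mean(config$vessel_radius_um)
  i_det <- array(config$reflectivity_vitreous, dim = c(nz, nx, ny))
  # membership by voxel centre: centre (k - 0.5) dz in [top, bot) means
  # k from ceil(top/dz + 0.5) to ceil(bot/dz + 0.5) - 1; fill by linear
  # index ranges (one pass per layer, no logical temporaries)
  fill_band <- function(arr, top, bot, value) {
    k0 <- pmin(pmax(ceiling(as.vector(top) / dz + 0.5), 1L), nz + 1L)
    k1 <- pmin(pmax(ceiling(as.vector(bot) / dz + 0.5) - 1L, 0L), nz)
    len <- pmax(k1 - k0 + 1L, 0L)
    sel <- len > 0L
    if (!any(sel)) return(arr)
    starts <- (which(sel) - 1L) * nz + k0[sel]
    idx <- rep(starts, len[sel]) + sequence(len[sel]) - 1L
    arr[idx] <- value
    arr
  }
  for (l in seq_len(6)) {
    i_det <- fill_band(i_det, bnd[[l]], bnd[[l + 1]], refl[l])
  }
  i_det <- fill_band(i_det, bnd[[7]], matrix(nz * dz + dz, nx, ny),
                     config$reflectivity_below)
  vox_vessel <- array(FALSE, dim = c(nz, nx, ny))
  for (px in names(vmask)) {
    cen <- plexus_band[[px]]
    cen[!vmask[[px]]] <- -1e6 # no fill outside the en-face mask
    vox_vessel <- fill_band(vox_vessel, cen - vr_mid, cen + vr_mid, TRUE)
  }
  i_det[vox_vessel] <- config$reflectivity_vessel
  i_det <- i_det * rep(snr_mult, each = nz)

  # --- speckle, repeats, noise -------------------------------------------
  nvox <- nz * nx * ny
  intensity <- array(0, dim = c(nz, nx, ny, config$n_repeats))
  e_common <- if (config$speckle) array(rexp(nvox), dim = dim(i_det)) else 1
  d <- config$decorr_level
  vidx <- which(vox_vessel)
  for (r in seq_len(config$n_repeats)) {
    e_r <- if (config$speckle) e_common else array(1, dim = dim(i_det))
    if (length(vidx) && d > 0) {
      e_r[vidx] <- (1 - d) * e_r[vidx] + d * rexp(length(vidx))
    }
    frame <- i_det * e_r
    if (config$noise_floor > 0) {
      frame <- frame + config$noise_floor * array(rexp(nvox), dim = dim(i_det))
    }
    intensity[, , , r] <- frame
  }

  # --- depolarization channel (RPE band, gap at the ONH) ------------------
  depol <- array(0.02, dim = c(nz, nx, ny))
  gap <- dist_onh < 0.8 * config$onh_radius_um
  rpe_top <- bnd$PRC_RPE
  rpe_top[gap] <- nz * dz + dz # no depolarizing band inside the ONH gap
  rpe_bot <- bnd$RPE_POST
  rpe_bot[gap] <- nz * dz + dz
  depol <- fill_band(depol, rpe_top, rpe_bot, 0.9)

  vol <- oct_volume(intensity, depol, dx_um = dx, dy_um = dy, dz_um = dz)
  truth <- structure(
    list(boundaries = bnd, vessel_masks = vmask, densities = densities,
         onh_center_um = config$onh_center_um,
         onh_radius_um = config$onh_radius_um,
         vox_vessel = vox_vessel, config = config),
    class = "phantom_truth"
  )
  list(volume = vol, truth = truth)
}

# Smooth zero-mean field with approximate amplitude `amp`: a sum of three
# random-phase low-order cosine modes.
smooth_field <- function(nx, ny, amp) {
  if (amp <= 0) return(matrix(0, nx, ny))
  f <- matrix(0, nx, ny)
  xs <- seq_len(nx) / nx; ys <- seq_len(ny) / ny
  for (k in 1:3) {
    fx <- sample(0:2, 1); fy <- sample(0:2, 1)
    if (fx == 0 && fy == 0) fx <- 1
    ph <- runif(2, 0, 2 * pi)
    f <- f + outer(cos(2 * pi * fx * xs + ph[1]),
                   cos(2 * pi * fy * ys + ph[2]))
  }
  amp * f / 3
}

# Stamp smoothed random-walk tube segments until the mask reaches the
# target area density (checked in physical um via anisotropic pixel
# spacings). Segment starts are uniform over a domain padded by the
# segment length, and walks are length-limited rather than clipped at a
# boundary, so coverage near the field border matches the interior; only
# in-field pixels count toward the density.
draw_vessel_mask <- function(nx, ny, dx, dy, target, radius_range,
                             segment_um = 150) {
  mask <- matrix(FALSE, nx, ny)
  if (target <= 0) return(mask)
  total <- nx * ny
  target_px <- ceiling(target * total)
  fov_x <- nx * dx; fov_y <- ny * dy
  pad <- segment_um + 2 * radius_range[2]
  n_px <- 0L
  for (tube in seq_len(20000L)) {
    r <- runif(1, radius_range[1], radius_range[2])
    pos <- c(runif(1, -pad, fov_x + pad), runif(1, -pad, fov_y + pad))
    ang <- runif(1, 0, 2 * pi)
    step <- max(r / 2, 2)
    for (s in seq_len(ceiling(segment_um / step))) {
      i0 <- pmax(1L, floor((pos[1] - r) / dx)); i1 <- pmin(nx, ceiling((pos[1] + r) / dx) + 1L)
      j0 <- pmax(1L, floor((pos[2] - r) / dy)); j1 <- pmin(ny, ceiling((pos[2] + r) / dy) + 1L)
      if (i1 >= i0 && j1 >= j0) {
        ii <- i0:i1; jj <- j0:j1
        d2 <- outer(((ii - 0.5) * dx - pos[1])^2, ((jj - 0.5) * dy - pos[2])^2, "+")
        sub <- mask[ii, jj, drop = FALSE]
        add <- which(d2 <= r^2 & !sub)
        if (length(add)) {
          need <- target_px - n_px
          if (length(add) > need) {
            # partial final stamp, nearest pixels first, so the realized
            # density lands within one pixel of the target
            add <- add[order(d2[add])][seq_len(need)]
          }
          sub[add] <- TRUE
          mask[ii, jj] <- sub
          n_px <- n_px + length(add)
        }
      }
      if (n_px >= target_px) return(mask)
      ang <- ang + rnorm(1, 0, 0.25)
      pos <- pos + step * c(cos(ang), sin(ang))
    }
  }
  mask
}
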