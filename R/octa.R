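# OCT angiography: decorrelation contrast, slab projection, vessel
# binarization, ONH cutout, SNR sector map and gated area density.

#' Compute angiography (decorrelation) contrast from repeated B-scans
#'
#' Motion contrast between repeated acquisitions: for every adjacent repeat
#' pair the amplitude correlation is computed per voxel over a local axial
#' window, and the decorrelation is one minus the mean pair correlation,
#' clipped to [0, 1]. Static voxels (shared speckle) give ~0; voxels whose
#' repeat amplitudes are independent (flow) give ~1.
#'
#' @param vol An [oct_volume()] with >= 2 repeats.
#' @param window Axial correlation window in pixels (odd).
#' @param lateral_window Optional lateral box window (pixels) over which the
#'   correlation moments are additionally pooled; 1 keeps the estimate
#'   per A-scan (sharpest vessel edges).
#' @param z_range_um Optional `c(zmin, zmax)` restricting the computation
#'   to a depth band (decorrelation outside is set to 0); used to skip
#'   signal-free depths when the retina's extent is already known.
#' @return 3-D decorrelation array `[nz, nx, ny]` in [0, 1].
#' @export
compute_octa <- function(vol, window = 9L, lateral_window = 1L, z_range_um = NULL) {
  if (!inherits(vol, "oct_volume")) abort_field("vol", "must be an oct_volume")
  n_rep <- dim(vol$intensity)[4]
  if (n_rep < 2L) abort_field("vol", "need at least 2 repeats")
  dims <- dim(vol$intensity)[1:3]
  nz <- dims[1]
  zc <- (seq_len(nz) - 0.5) * vol$dz_um
  zsel <- if (is.null(z_range_um)) seq_len(nz) else {
    which(zc >= z_range_um[1] & zc <= z_range_um[2])
  }
  if (!length(zsel)) abort_field("z_range_um", "selects no depth pixels")
  eps <- 1e-12
  nzs <- length(zsel)
  acc <- matrix(0, nzs, dims[2] * dims[3])
  # moments over an axial x lateral window: axial running mean per A-scan,
  # then a 3x3 lateral box per depth slice (window_lat = 1 disables)
  win_mean <- function(a, window_lat = lateral_window) {
    m <- run_mean_cols(a, window)
    if (window_lat > 1L) {
      arr <- array(m, dim = c(nzs, dims[2], dims[3]))
      for (k in seq_len(nzs)) arr[k, , ] <- box_mean2(arr[k, , ], window_lat)
      m <- matrix(arr, nzs)
    }
    m
  }
  # per-repeat amplitude moments are cached and reused by adjacent pairs
  a_prev <- matrix(sqrt(vol$intensity[zsel, , , 1]), nzs)
  m_prev <- win_mean(a_prev)
  v_prev <- pmax(win_mean(a_prev * a_prev) - m_prev^2, 0)
  for (r in seq_len(n_rep - 1L)) {
    a_next <- matrix(sqrt(vol$intensity[zsel, , , r + 1L]), nzs)
    m_next <- win_mean(a_next)
    v_next <- pmax(win_mean(a_next * a_next) - m_next^2, 0)
    cov12 <- win_mean(a_prev * a_next) - m_prev * m_next
    corr <- (cov12 + eps) / (sqrt(v_prev * v_next) + eps)
    acc <- acc + pmin(pmax(1 - corr, 0), 1)
    a_prev <- a_next; m_prev <- m_next; v_prev <- v_next
  }
  out <- array(0, dim = dims)
  out[zsel, , ] <- acc / (n_rep - 1L)
  attr(out, "n_pairs") <- n_rep - 1L
  out
}

#' Estimate the noise floor from the signal-free vitreous band
#'
#' Mean plus two standard deviations of the repeat-averaged intensity in a
#' shallow band above the innermost detected ILM of the flattened volume.
#'
#' @param flat Flattened [oct_volume()].
#' @param surfaces `layer_surfaces` for the same volume.
#' @param gap_um Margin kept between the band and the shallowest ILM.
#' @return Noise floor (intensity units, > 0).
#' @export
estimate_noise_floor <- function(flat, surfaces, gap_um = 15) {
  nz <- dim(flat$intensity)[1]
  zc <- (seq_len(nz) - 0.5) * flat$dz_um
  zmax <- min(surfaces$boundaries$ILM) - gap_um
  band <- which(zc < zmax & zc > 2 * flat$dz_um)
  if (length(band) < 3L) {
    stop("no signal-free band above the ILM to estimate the noise floor",
         call. = FALSE)
  }
  m <- mean_over_repeats(flat$intensity)[band, , ]
  max(mean(m) + 2 * sd(m), 1e-12)
}

#' Project the three vascular plexus slabs
#'
#' Maximum-projects the decorrelation volume within the three plexus slabs
#' defined by the layer segmentation — SVP within [ILM, RNFL/GCL-IPL), ICP
#' within [RNFL/GCL-IPL, INL-OPL), DCP within [INL-OPL, OPL-PRC) — and
#' mean-projects the structural intensity over the same slabs for SNR.
#' Pixels with a degenerate (sub-pixel) slab are marked invalid.
#'
#' @param decorr Decorrelation volume from [compute_octa()].
#' @param flat The flattened [oct_volume()] the decorrelation came from.
#' @param surfaces `layer_surfaces` from [segment_layers()].
#' @param noise_floor Optional noise floor; estimated via
#'   [estimate_noise_floor()] when NULL.
#' @return Named list of three `angio_enface` objects (`SVP`, `ICP`,
#'   `DCP`), each with `decorr`, `signal`, `noise_floor`, ONH annotation
#'   and spacings.
#' @export
project_slabs <- function(decorr, flat, surfaces, noise_floor = NULL) {
  if (!inherits(surfaces, "layer_surfaces")) {
    abort_field("surfaces", "must be a layer_surfaces object")
  }
  dims <- dim(decorr)
  nz <- dims[1]; nx <- dims[2]; ny <- dims[3]
  zc <- (seq_len(nz) - 0.5) * flat$dz_um
  b <- surfaces$boundaries
  slabs <- list(
    SVP = list(top = b$ILM, bot = b$RNFL_GCL_IPL),
    ICP = list(top = b$RNFL_GCL_IPL, bot = b$INL_OPL),
    DCP = list(top = b$INL_OPL, bot = b$OPL_PRC)
  )
  if (is.null(noise_floor)) noise_floor <- estimate_noise_floor(flat, surfaces)
  struct <- mean_over_repeats(flat$intensity)

  purrr::imap(slabs, function(sl, px) {
    dec <- matrix(0, nx, ny)
    sig <- matrix(0, nx, ny)
    invalid <- matrix(FALSE, nx, ny)
    for (j in seq_len(ny)) {
      m <- outer(zc, sl$top[, j], ">=") & outer(zc, sl$bot[, j], "<")
      cnt <- colSums(m)
      dm <- decorr[, , j]; sm <- struct[, , j]
      dm[!m] <- -Inf; sm[!m] <- 0
      dec[, j] <- dm[cbind(max.col(t(dm), ties.method = "first"), seq_len(nx))]
      sig[, j] <- colSums(sm) / pmax(cnt, 1L)
      invalid[, j] <- cnt == 0L
    }
    dec[invalid] <- 0
    structure(
      list(plexus = px, decorr = dec, signal = sig, invalid = invalid,
           noise_floor = noise_floor,
           onh_center_um = surfaces$onh_center_um,
           dx_um = surfaces$dx_um, dy_um = surfaces$dy_um),
      class = "angio_enface"
    )
  })
}

#' Binarize an en-face angiogram into a vessel mask
#'
#' A pixel is vessel when three conditions hold: (1) the structural slab
#' signal is at least `signal_mult` times the noise floor (quality gate);
#' (2) the decorrelation (flow) value is at or above the flow cutoff
#' (Otsu's threshold on the decorrelation histogram of quality-gated
#' pixels by default) — this carries the vessel shape, since the
#' decorrelation transition at a vessel edge is sharp; and (3) the pixel
#' lies within the Frangi vesselness support of the decorrelation map —
#' hysteresis thresholding of the multiscale vesselness (strong = Otsu on
#' the vesselness histogram, weak = a quarter of it, weak regions kept only
#' when connected to strong ones), dilated by one pixel so that tube
#' interiors and junctions, where a ridge filter responds weakly, stay
#' covered. The Frangi support verifies curvilinear shape and rejects
#' isolated decorrelation speckle; the flow threshold fixes the area.
#' A frame of `margin` pixels at the image border is then set to zero and
#' excluded from analysis.
#'
#' @param enface An `angio_enface` from [project_slabs()].
#' @param margin Border margin in pixels.
#' @param signal_mult Signal gate as a multiple of the noise floor.
#' @param flow_cutoff Decorrelation cutoff; `NULL` for Otsu.
#' @param cutoff Strong vesselness cutoff; `NULL` for Otsu.
#' @param weak_frac Weak (hysteresis) cutoff as a fraction of the strong.
#' @param scales Frangi scales in pixels.
#' @return A `vessel_mask`: binary mask, excluded-pixel mask, margin,
#'   ONH-cutout bookkeeping and spacings.
#' @export
binarize_vessels <- function(enface, margin = 10L, signal_mult = 10,
                             flow_cutoff = NULL, cutoff = NULL,
                             weak_frac = 0.25, scales = 1:4) {
  if (!inherits(enface, "angio_enface")) {
    abort_field("enface", "must be an angio_enface")
  }
  quality <- enface$signal >= signal_mult * enface$noise_floor & !enface$invalid
  if (is.null(flow_cutoff)) {
    flow_cutoff <- otsu_cutoff(enface$decorr * quality)
  }
  v <- frangi_vesselness(enface$decorr, scales = scales)
  if (is.null(cutoff)) cutoff <- otsu_cutoff(v)
  support <- hysteresis_support(v, cutoff, weak_frac * cutoff)
  support <- EBImage::dilate(support * 1, EBImage::makeBrush(3, "box")) > 0
  mask <- quality & enface$decorr >= flow_cutoff & support
  nx <- nrow(mask); ny <- ncol(mask)
  excluded <- matrix(FALSE, nx, ny)
  if (margin > 0) {
    excluded[c(seq_len(margin), nx - seq_len(margin) + 1L), ] <- TRUE
    excluded[, c(seq_len(margin), ny - seq_len(margin) + 1L)] <- TRUE
  }
  mask[excluded] <- FALSE
  structure(
    list(mask = mask, excluded = excluded, margin = as.integer(margin),
         onh_cut_radius_um = 0,
         plexus = enface$plexus,
         onh_center_um = enface$onh_center_um,
         dx_um = enface$dx_um, dy_um = enface$dy_um),
    class = "vessel_mask"
  )
}

#' Cut out the ONH disc from a vessel mask
#'
#' Zeroes every pixel closer than `radius_um` to the ONH center (physical
#' micrometres) and flags it excluded from analysis.
#'
#' @param mask A `vessel_mask`.
#' @param center_um ONH center; defaults to the mask's annotation.
#' @param radius_um Cutout radius in micrometres.
#' @return The modified `vessel_mask`.
#' @export
cut_onh <- function(mask, center_um = mask$onh_center_um, radius_um = 100) {
  if (!inherits(mask, "vessel_mask")) abort_field("mask", "must be a vessel_mask")
  check_scalar_num(radius_um, "radius_um", lower = 0)
  if (radius_um == 0) return(mask)
  nx <- nrow(mask$mask); ny <- ncol(mask$mask)
  co <- enface_coords(nx, ny, mask$dx_um, mask$dy_um)
  dist <- sqrt(outer((co$x - center_um[1])^2, rep(1, ny)) +
                 outer(rep(1, nx), (co$y - center_um[2])^2))
  inside <- dist < radius_um
  mask$mask[inside] <- FALSE
  mask$excluded <- mask$excluded | inside
  mask$onh_cut_radius_um <- radius_um
  mask$onh_center_um <- center_um
  mask
}

#' SNR sector map: quadrants by diagonals, concentric rings
#'
#' Assigns every pixel to a zone — one of the four diagonal quadrants
#' around the ONH center crossed with 100 um-wide concentric rings
#' (half-open, ring index floor(dist / ring width)) — and computes each
#' zone's SNR as the mean structural slab signal over the zone divided by
#' the noise floor.
#'
#' @param enface An `angio_enface`.
#' @param ring_width_um Ring width in micrometres.
#' @return A `sector_grid`: integer quadrant and ring label maps and a
#'   `zones` tibble (quadrant, ring, n_pixels, snr, empty).
#' @export
snr_sector_map <- function(enface, ring_width_um = 100) {
  if (!inherits(enface, "angio_enface")) {
    abort_field("enface", "must be an angio_enface")
  }
  check_scalar_num(ring_width_um, "ring_width_um", lower = 1e-9)
  nx <- nrow(enface$signal); ny <- ncol(enface$signal)
  co <- enface_coords(nx, ny, enface$dx_um, enface$dy_um)
  dxm <- outer(co$x - enface$onh_center_um[1], rep(1, ny))
  dym <- outer(rep(1, nx), co$y - enface$onh_center_um[2])
  dist <- sqrt(dxm^2 + dym^2)
  quad <- matrix(match(sector_labels(dxm, dym),
                       c("superior", "nasal", "inferior", "temporal")) - 1L,
                 nx, ny)
  ring <- matrix(as.integer(floor(dist / ring_width_um)), nx, ny)
  key <- quad * (max(ring) + 1L) + ring
  zones <- tibble(
    quadrant = as.integer(names(tapply(enface$signal, key, mean))) %/% (max(ring) + 1L),
    ring = as.integer(names(tapply(enface$signal, key, mean))) %% (max(ring) + 1L),
    n_pixels = as.integer(tapply(rep(1L, length(key)), key, sum)),
    snr = as.numeric(tapply(enface$signal, key, mean)) / enface$noise_floor
  )
  zones$empty <- zones$n_pixels == 0L
  structure(
    list(quad = quad, ring = ring, zones = zones,
         ring_width_um = ring_width_um, noise_floor = enface$noise_floor,
         onh_center_um = enface$onh_center_um),
    class = "sector_grid"
  )
}

#' SNR-gated area vessel density
#'
#' Removes zones whose SNR is below the plexus-specific gate (20x the
#' noise floor for SVP and ICP, 15x for DCP), counts vessel (positive) and
#' non-vessel (negative) pixels in the remaining zones — excluding the
#' border margin and the ONH cutout — and reports the area density
#' 100 * positive / (positive + negative). With no zone above the gate the
#' result is flagged missing rather than zero, mirroring the exclusion of
#' unusable measurements.
#'
#' @param mask A `vessel_mask` (after [cut_onh()]).
#' @param grid A `sector_grid` from [snr_sector_map()].
#' @param plexus "SVP", "ICP" or "DCP" (sets the default gate).
#' @param gate Optional explicit SNR gate.
#' @return One-row tibble: `plexus`, `density_pct`, `n_pos`, `n_neg`,
#'   `n_zones_included`, `n_zones_excluded`, `missing`.
#' @export
gated_vessel_density <- function(mask, grid, plexus = mask$plexus, gate = NULL) {
  if (!inherits(mask, "vessel_mask")) abort_field("mask", "must be a vessel_mask")
  if (!inherits(grid, "sector_grid")) abort_field("grid", "must be a sector_grid")
  if (!plexus %in% c("SVP", "ICP", "DCP")) {
    abort_field("plexus", "must be SVP, ICP or DCP")
  }
  if (is.null(gate)) gate <- if (plexus == "DCP") 15 else 20
  zin <- dplyr::filter(grid$zones, !.data$empty, .data$snr >= gate)
  zex <- nrow(grid$zones) - nrow(zin)
  if (nrow(zin) == 0L) {
    return(tibble(plexus = plexus, density_pct = NA_real_, n_pos = 0L,
                  n_neg = 0L, n_zones_included = 0L,
                  n_zones_excluded = zex, missing = TRUE))
  }
  nringp1 <- max(grid$ring) + 1L
  key <- grid$quad * nringp1 + grid$ring
  inc_keys <- zin$quadrant * nringp1 + zin$ring
  analysis <- matrix(key %in% inc_keys, nrow(key), ncol(key)) & !mask$excluded
  n_pos <- sum(mask$mask & analysis)
  n_neg <- sum(!mask$mask & analysis)
  tibble(plexus = plexus,
         density_pct = 100 * n_pos / (n_pos + n_neg),
         n_pos = n_pos, n_neg = n_neg,
         n_zones_included = nrow(zin), n_zones_excluded = zex,
         missing = FALSE)
}

#' End-to-end vessel density for the three plexuses
#'
#' Convenience wrapper chaining [compute_octa()], [project_slabs()],
#' [binarize_vessels()], [cut_onh()], [snr_sector_map()] and
#' [gated_vessel_density()] for the SVP, ICP and DCP.
#'
#' @param flat Flattened [oct_volume()].
#' @param surfaces `layer_surfaces` from [segment_layers()].
#' @param onh_radius_um ONH cutout radius.
#' @param margin Border margin in pixels.
#' @param ring_width_um SNR ring width.
#' @param window Axial correlation window passed to [compute_octa()].
#' @return Tibble with one row per plexus (see [gated_vessel_density()]).
#' @export
vessel_density <- function(flat, surfaces, onh_radius_um = 100, margin = 10L,
                           ring_width_um = 100, window = 5L) {
  # a short axial window keeps flow contrast localized, so vessels in one
  # plexus do not smear across the slab boundary into a neighbour
  zr <- c(max(min(surfaces$boundaries$ILM) - 10, 0),
          max(surfaces$boundaries$OPL_PRC) + 10)
  decorr <- compute_octa(flat, window = window, z_range_um = zr)
  enf <- project_slabs(decorr, flat, surfaces)
  purrr::map_dfr(enf, function(e) {
    m <- binarize_vessels(e, margin = margin)
    m <- cut_onh(m, radius_um = onh_radius_um)
    g <- snr_sector_map(e, ring_width_um = ring_width_um)
    gated_vessel_density(m, g)
  })
}
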