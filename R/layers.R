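# Layer analysis: depolarization-based flattening, boundary segmentation,
# en-face thickness maps and ONH annulus/sector averages.

#' Flatten an OCT volume with respect to the depolarizing RPE
#'
#' Locates the retinal pigment epithelium in every A-scan as the
#' depolarization-weighted centroid depth, smooths the resulting depth map
#' laterally, and shifts each A-scan axially (sub-pixel, by linear
#' interpolation) so the RPE
#' sits at a common reference depth. A-scans without depolarizing signal
#' (e.g. the ONH) are marked invalid and in-painted from their neighbours;
#' more than 30% invalid A-scans raises an error, mirroring quality
#' exclusion of unusable scans.
#'
#' @param vol An [oct_volume()] with a depolarization channel.
#' @param z_ref_um Reference depth for the flattened RPE; default the
#'   median detected RPE depth (so an already-flat volume is returned
#'   unchanged).
#' @param max_invalid Maximum tolerated fraction of invalid A-scans.
#' @return An [oct_volume()] with extra fields `rpe_depth_um` (the smoothed
#'   en-face RPE depth map after flattening reference removal), `invalid`
#'   (logical en-face mask), `shifts_px`, and `z_ref_um`.
#' @export
flatten_volume <- function(vol, z_ref_um = NULL, max_invalid = 0.30) {
  if (!inherits(vol, "oct_volume")) abort_field("vol", "must be an oct_volume")
  if (is.null(vol$depol)) abort_field("vol", "depolarization channel required")
  nz <- dim(vol$intensity)[1]; nx <- dim(vol$intensity)[2]; ny <- dim(vol$intensity)[3]
  zc <- (seq_len(nz) - 0.5) * vol$dz_um

  w <- pmax(vol$depol - 0.5, 0)
  wsum <- colSums(matrix(w, nz))
  depth <- colSums(matrix(w * zc, nz))
  invalid <- wsum <= 0
  frac_bad <- mean(invalid)
  if (frac_bad > max_invalid) {
    stop(sprintf("%.0f%% of A-scans lack depolarizing signal (limit %.0f%%)",
                 100 * frac_bad, 100 * max_invalid), call. = FALSE)
  }
  depth[!invalid] <- depth[!invalid] / wsum[!invalid]
  dmap <- matrix(depth, nx, ny)
  inval <- matrix(invalid, nx, ny)

  # in-paint invalid A-scans by normalized box blur over valid neighbours
  if (any(inval)) {
    wts <- box_mean2(1 - inval * 1, 31L)
    num <- box_mean2(ifelse(inval, 0, dmap), 31L)
    dmap[inval] <- (num / pmax(wts, 1e-9))[inval]
  }
  smoothed <- box_mean2(median2(dmap, 5L), 7L)

  if (is.null(z_ref_um)) z_ref_um <- median(smoothed)
  shift_um <- z_ref_um - smoothed
  flat_int <- shift_axially(vol$intensity, shift_um / vol$dz_um)
  flat_dep <- shift_axially(vol$depol, shift_um / vol$dz_um)

  out <- oct_volume(flat_int, pmin(pmax(flat_dep, 0), 1),
                    vol$dx_um, vol$dy_um, vol$dz_um)
  out$rpe_depth_um <- smoothed + shift_um
  out$invalid <- inval
  out$shift_um <- matrix(shift_um, nx, ny)
  out$z_ref_um <- z_ref_um
  out
}

# shift each A-scan down by a (possibly fractional) pixel count via linear
# interpolation, zero fill; integer shifts are grouped into block copies.
# Processed one repeat at a time to bound peak memory.
shift_axially <- function(arr, shifts_px) {
  s_int <- as.integer(floor(shifts_px))
  frac <- as.vector(shifts_px - s_int)
  dims <- dim(arr)
  nz <- dims[1]
  n_rep <- if (length(dims) == 4L) dims[4] else 1L
  pure_int <- all(frac == 0)
  groups <- split(seq_along(s_int), s_int)
  out <- array(0, dim = dims)
  for (r in seq_len(n_rep)) {
    m_in <- matrix(if (n_rep == 1L) arr else arr[, , , r], nz)
    m_out <- matrix(0, nz, ncol(m_in))
    for (sname in names(groups)) {
      s <- as.integer(sname)
      cols <- groups[[sname]]
      dst <- seq_len(nz) + s
      ok <- dst >= 1L & dst <= nz
      if (pure_int) {
        m_out[dst[ok], cols] <- m_in[which(ok), cols]
      } else {
        # linear interpolation between integer shifts s and s + 1:
        # out[z] = (1 - f) in[z - s] + f in[z - s - 1]
        src <- which(ok)
        m_out[src + s, cols] <- m_in[src, cols, drop = FALSE] *
          rep(1 - frac[cols], each = length(src))
        src2 <- which(dst >= 0L & dst <= nz - 1L) # rows with src + s + 1 in range
        m_out[src2 + s + 1L, cols] <- m_out[src2 + s + 1L, cols, drop = FALSE] +
          m_in[src2, cols, drop = FALSE] * rep(frac[cols], each = length(src2))
      }
    }
    if (n_rep == 1L) out <- array(m_out, dims) else out[, , , r] <- m_out
  }
  out
}

#' Auto-detect the ONH center from the depolarization gap
#'
#' Convenience detector: the optic nerve head interrupts the depolarizing
#' RPE band, so its center is estimated as the centroid of A-scans without
#' depolarizing signal. Intended as a starting point only; analyses take
#' the ONH center as an explicit annotation and never call this silently.
#'
#' @param vol An [oct_volume()] with a depolarization channel.
#' @return ONH center `c(x_um, y_um)`.
#' @export
detect_onh <- function(vol) {
  if (is.null(vol$depol)) abort_field("vol", "depolarization channel required")
  nz <- dim(vol$depol)[1]; nx <- dim(vol$depol)[2]; ny <- dim(vol$depol)[3]
  gap <- matrix(colSums(matrix(vol$depol > 0.5, nz)) == 0, nx, ny)
  if (!any(gap)) abort_field("vol", "no depolarization gap found")
  co <- enface_coords(nx, ny, vol$dx_um, vol$dy_um)
  idx <- which(gap, arr.ind = TRUE)
  c(mean(co$x[idx[, 1]]), mean(co$y[idx[, 2]]))
}

# per-boundary gradient sign and search band (um beyond previous boundary)
boundary_priors <- function() {
  tibble(
    boundary = boundary_names(),
    sign = c(1, -1, -1, 1, -1, 1, -1),
    # lower offsets clear the axially smeared edge of the previous boundary
    lo = c(NA, 12, 10, 10, 8, 10, 10),
    hi = c(NA, 85, 55, 55, 40, 150, 60)
  )
}

#' Segment retinal layer boundaries
#'
#' Finds the seven boundary surfaces (ILM, RNFL/GCL-IPL, IPL-INL, INL-OPL,
#' OPL-PRC, PRC-RPE, RPE posterior) in a flattened volume by an axial
#' intensity-gradient search within anatomically ordered bands: the ILM is
#' the first strong positive gradient above the RPE reference, and each
#' subsequent boundary is the sign-matched gradient extremum within a
#' bounded offset from the previous one. Boundary maps are median-smoothed
#' laterally (15 px window) and ordering is enforced by projection.
#'
#' @param flat A flattened [oct_volume()] from [flatten_volume()].
#' @param onh_center_um ONH center annotation `c(x_um, y_um)` (manual, or
#'   from [detect_onh()]).
#' @param onh_radius_um ONH exclusion radius for downstream analyses.
#' @param median_window Lateral median-smoothing window in pixels.
#' @return A `layer_surfaces` object: list of 7 boundary depth maps (um,
#'   en-face grids), ONH annotation, spacings and the valid-pixel mask.
#' @export
segment_layers <- function(flat, onh_center_um, onh_radius_um = 100,
                           median_window = 15L) {
  if (!inherits(flat, "oct_volume")) abort_field("flat", "must be an oct_volume")
  if (is.null(flat$z_ref_um)) abort_field("flat", "volume must be flattened first")
  nz <- dim(flat$intensity)[1]; nx <- dim(flat$intensity)[2]; ny <- dim(flat$intensity)[3]
  dz <- flat$dz_um
  z_ref <- flat$z_ref_um
  # the retina lives in a bounded band around the RPE reference; restrict
  # all processing to it
  zsel <- which((seq_len(nz) - 0.5) * dz >= z_ref - 330 &
                  (seq_len(nz) - 0.5) * dz <= z_ref + 80)
  if (length(zsel) < 16L) abort_field("flat", "reference depth leaves no search band")
  nzs <- length(zsel)
  z_off <- zsel[1] - 1L

  # repeat-mean, light lateral box smoothing per depth slice
  vol <- mean_over_repeats_band(flat$intensity, zsel)
  for (k in seq_len(nzs)) vol[k, , ] <- box_mean2(vol[k, , ], 5L)
  # axial [1,2,1]/4 smoothing
  vol[2:(nzs - 1), , ] <- (vol[1:(nzs - 2), , ] + 2 * vol[2:(nzs - 1), , ] +
                             vol[3:nzs, , ]) / 4

  priors <- boundary_priors()
  bnd <- purrr::map(seq_len(7), ~ matrix(NA_real_, nx, ny))
  names(bnd) <- priors$boundary

  for (j in seq_len(ny)) {
    sl <- vol[, , j]
    g <- sl[2:nzs, , drop = FALSE] - sl[1:(nzs - 1), , drop = FALSE]
    gz <- (z_off + seq_len(nzs - 1)) * dz # plane between voxels k, k+1

    # ILM: first local gradient peak above half the window max, searched in
    # a wide band above the RPE reference (first, not global, so the
    # vitreous-to-RNFL edge wins over deeper bright transitions)
    win <- gz >= z_ref - 300 & gz <= z_ref - 5
    gilm <- g
    gilm[!win, ] <- -Inf
    cmax <- apply(gilm, 2, max)
    is_peak <- gilm >= rbind(gilm[-1, , drop = FALSE], -Inf) &
      gilm >= rep(pmax(cmax, 1e-9), each = nzs - 1) * 0.5 & gilm > 0
    first_strong <- max.col(t(is_peak * 1), ties.method = "first")
    none <- cmax <= 0
    first_strong[none] <- which.min(abs(gz - (z_ref - 200)))
    prev <- gz[first_strong] + subpixel_offset(g, first_strong) * dz
    bnd[[1]][, j] <- prev

    for (b in 2:7) {
      lo <- prev + priors$lo[b]
      hi <- prev + priors$hi[b]
      gs <- g * priors$sign[b]
      mask <- outer(gz, lo, ">=") & outer(gz, hi, "<=")
      gs[!mask] <- -Inf
      pick <- max.col(t(gs), ties.method = "first")
      best <- gs[cbind(pick, seq_len(nx))]
      fallback <- !is.finite(best) | best <= 0
      depth_b <- gz[pick] + subpixel_offset(g * priors$sign[b], pick) * dz
      depth_b[fallback] <- (prev + priors$lo[b])[fallback]
      prev <- depth_b
      bnd[[b]][, j] <- depth_b
    }
  }

  # lateral median as outlier rejection: keep the sub-pixel estimate where
  # it agrees with the local median, replace it where it deviates grossly
  # (vessel shadows, speckle dropouts)
  bnd <- purrr::map(bnd, function(raw) {
    med <- median2(raw, median_window)
    ifelse(abs(raw - med) > 2 * dz, med, raw)
  })
  for (b in 2:7) bnd[[b]] <- pmax(bnd[[b]], bnd[[b - 1]] + 1e-6)
  for (b in 2:7) {
    if (any(bnd[[b]] <= bnd[[b - 1]])) {
      stop(sprintf("boundary ordering violated at %s", names(bnd)[b]), call. = FALSE)
    }
  }

  structure(
    list(boundaries = bnd,
         onh_center_um = onh_center_um, onh_radius_um = onh_radius_um,
         dx_um = flat$dx_um, dy_um = flat$dy_um, dz_um = dz,
         valid = !(flat$invalid %||% matrix(FALSE, nx, ny))),
    class = "layer_surfaces"
  )
}

# sub-pixel refinement of a per-column gradient extremum: centroid of the
# (sign-adjusted, positive-clamped) gradient lobe around the pick, which
# locates the centre of a laterally smeared transition
subpixel_offset <- function(g, pick, halfwin = 3L) {
  n <- nrow(g)
  cols <- seq_along(pick)
  num <- 0; den <- 0
  for (o in -halfwin:halfwin) {
    k <- pmin(pmax(pick + o, 1L), n)
    w <- pmax(g[cbind(k, cols)], 0)
    w[!is.finite(w)] <- 0
    num <- num + w * o
    den <- den + w
  }
  off <- ifelse(den > 1e-12, num / den, 0)
  pmin(pmax(off, -halfwin), halfwin)
}

mean_over_repeats <- function(intensity) {
  d <- dim(intensity)
  if (length(d) == 3L) return(intensity)
  out <- intensity[, , , 1]
  if (d[4] > 1L) for (r in 2:d[4]) out <- out + intensity[, , , r]
  out / d[4]
}

mean_over_repeats_band <- function(intensity, zsel) {
  d <- dim(intensity)
  if (length(d) == 3L) return(intensity[zsel, , , drop = FALSE])
  out <- intensity[zsel, , , 1]
  if (d[4] > 1L) for (r in 2:d[4]) out <- out + intensity[zsel, , , r]
  out / d[4]
}

#' En-face layer thickness maps
#'
#' Derives the nine standard thickness maps from segmented boundaries:
#' TOTAL (ILM to RPE posterior), the inner retinal complex IRL
#' (RNFL/GCL + IPL + INL), the outer complex ORL (OPL + PRC + RPE), and
#' the six sublayers. The composition identities TOTAL = IRL + ORL,
#' IRL = RNFL/GCL + IPL + INL and ORL = OPL + PRC + RPE hold exactly,
#' pixel-wise, by construction.
#'
#' @param surfaces A `layer_surfaces` object from [segment_layers()].
#' @return Named list of `thickness_map` objects (`TOTAL`, `IRL`, `ORL`,
#'   `RNFL_GCL`, `IPL`, `INL`, `OPL`, `PRC`, `RPE`), each holding en-face
#'   values in um, the ONH annotation and the valid mask.
#' @export
thickness_maps <- function(surfaces) {
  if (!inherits(surfaces, "layer_surfaces")) {
    abort_field("surfaces", "must be a layer_surfaces object")
  }
  b <- surfaces$boundaries
  vals <- list(
    TOTAL = b$RPE_POST - b$ILM,
    IRL = b$INL_OPL - b$ILM,
    ORL = b$RPE_POST - b$INL_OPL,
    RNFL_GCL = b$RNFL_GCL_IPL - b$ILM,
    IPL = b$IPL_INL - b$RNFL_GCL_IPL,
    INL = b$INL_OPL - b$IPL_INL,
    OPL = b$OPL_PRC - b$INL_OPL,
    PRC = b$PRC_RPE - b$OPL_PRC,
    RPE = b$RPE_POST - b$PRC_RPE
  )
  purrr::imap(vals, function(v, nm) {
    structure(
      list(layer = nm, values = v,
           onh_center_um = surfaces$onh_center_um,
           onh_radius_um = surfaces$onh_radius_um,
           dx_um = surfaces$dx_um, dy_um = surfaces$dy_um,
           valid = surfaces$valid),
      class = "thickness_map"
    )
  })
}

#' Annulus and sector thickness averages around the ONH
#'
#' Averages a thickness map over the annulus `[r_in, r_out)` around the ONH
#' center (physical micrometres, anisotropic spacings respected, half-open
#' radial test on pixel centres) and within the four sectors formed by the
#' diagonals through the ONH center: superior (image top), nasal (right),
#' inferior (bottom), temporal (left). The overall mean is the
#' pixel-count-weighted mean of the sector means. Anatomical orientation
#' depends on eye laterality; labels refer to the image frame.
#'
#' @param map A `thickness_map`.
#' @param r_in,r_out Annulus radii in micrometres, `r_in < r_out`.
#' @return A tibble: rows `superior`, `nasal`, `inferior`, `temporal`,
#'   `overall` with `mean_um` and `n_pixels`; annulus radii as attributes.
#' @export
annulus_sector_average <- function(map, r_in = 200, r_out = 600) {
  if (!inherits(map, "thickness_map")) abort_field("map", "must be a thickness_map")
  check_scalar_num(r_in, "r_in", lower = 0)
  check_scalar_num(r_out, "r_out", lower = 0)
  if (r_in >= r_out) abort_field("r_in", "must be < r_out")
  nx <- nrow(map$values); ny <- ncol(map$values)
  co <- enface_coords(nx, ny, map$dx_um, map$dy_um)
  dxm <- outer(co$x - map$onh_center_um[1], rep(1, ny))
  dym <- outer(rep(1, nx), co$y - map$onh_center_um[2])
  dist <- sqrt(dxm^2 + dym^2)
  in_ann <- dist >= r_in & dist < r_out & map$valid
  if (!any(in_ann)) {
    stop("annulus contains no pixels inside the field of view", call. = FALSE)
  }
  sect <- sector_labels(dxm, dym)
  rows <- purrr::map_dfr(c("superior", "nasal", "inferior", "temporal"), function(s) {
    sel <- in_ann & sect == s
    tibble(sector = s,
           mean_um = if (any(sel)) mean(map$values[sel]) else NA_real_,
           n_pixels = sum(sel))
  })
  overall <- tibble(
    sector = "overall",
    mean_um = sum(rows$mean_um * rows$n_pixels, na.rm = TRUE) /
      sum(rows$n_pixels[!is.na(rows$mean_um)]),
    n_pixels = sum(rows$n_pixels)
  )
  out <- dplyr::bind_rows(rows, overall)
  attr(out, "r_in_um") <- r_in
  attr(out, "r_out_um") <- r_out
  attr(out, "layer") <- map$layer
  out
}

# sector by the diagonals: half-open angular bins in the image frame
# (x right, y down): nasal [-45, 45), inferior [45, 135),
# temporal [135, 225), superior [225, 315) degrees
sector_labels <- function(dxm, dym) {
  ang <- (atan2(dym, dxm) + pi / 4) %% (2 * pi) # rotate so bins start at 0
  lab <- c("nasal", "inferior", "temporal", "superior")
  m <- findInterval(ang, c(0, pi / 2, pi, 3 * pi / 2))
  matrix(lab[m], nrow(dxm), ncol(dxm))
}
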