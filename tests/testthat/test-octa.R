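make_enface <- function(decorr, signal, floor = 1, dx = 4, dy = 4,
                        center = NULL, plexus = "SVP") {
  nx <- nrow(decorr); ny <- ncol(decorr)
  if (is.null(center)) center <- c(nx * dx / 2, ny * dy / 2)
  structure(
    list(plexus = plexus, decorr = decorr, signal = signal,
         invalid = matrix(FALSE, nx, ny), noise_floor = floor,
         onh_center_um = center, dx_um = dx, dy_um = dy),
    class = "angio_enface"
  )
}

make_mask <- function(mask, dx = 4, dy = 4, center = NULL, plexus = "SVP") {
  nx <- nrow(mask); ny <- ncol(mask)
  if (is.null(center)) center <- c(nx * dx / 2, ny * dy / 2)
  structure(
    list(mask = mask, excluded = matrix(FALSE, nx, ny), margin = 0L,
         onh_cut_radius_um = 0, plexus = plexus,
         onh_center_um = center, dx_um = dx, dy_um = dy),
    class = "vessel_mask"
  )
}

test_that("identical repeats give zero decorrelation; pair count is repeats - 1", {
  one <- array(rexp(20 * 8 * 6), dim = c(20, 8, 6))
  vol <- oct_volume(array(rep(one, 5), dim = c(20, 8, 6, 5)),
                    NULL, 4, 5, 1.5)
  d <- compute_octa(vol)
  expect_equal(max(abs(d)), 0)
  expect_equal(attr(d, "n_pairs"), 4L)
  single <- oct_volume(array(one, dim = c(20, 8, 6, 1)), NULL, 4, 5, 1.5)
  expect_error(compute_octa(single), "repeats")
})

test_that("vessel voxels decorrelate strongly against static voxels", {
  cfg <- tiny_phantom_config(seed = 5)
  ph <- generate_phantom(cfg)
  fl <- flatten_volume(ph$volume)
  d <- compute_octa(fl, window = 5L)
  vox <- ph$truth$vox_vessel
  expect_gt(mean(d[vox]) - mean(d[!vox & fl$intensity[, , , 1] > 0.05]), 0.5)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("slab projections respect phantom vessel placement and max monotonicity", {
  cfg <- tiny_phantom_config(vessel_density = c(SVP = 0.15, ICP = 0, DCP = 0),
                             seed = 9)
  ph <- generate_phantom(cfg)
  fl <- flatten_volume(ph$volume)
  sf <- segment_layers(fl, onh_center_um = cfg$onh_center_um)
  d <- compute_octa(fl, window = 5L)
  enf <- project_slabs(d, fl, sf)
  svp_mask <- ph$truth$vessel_masks$SVP
  expect_gt(mean(enf$SVP$decorr[svp_mask]), mean(enf$ICP$decorr[svp_mask]) + 0.2)
  expect_gt(mean(enf$SVP$decorr[svp_mask]), mean(enf$DCP$decorr[svp_mask]) + 0.2)
  # projection of a slab never exceeds the full-depth max projection
  full_max <- apply(d, c(2, 3), max)
  for (px in names(enf)) {
    expect_true(all(enf[[px]]$decorr <= full_max + 1e-12))
  }
  # all-zero volume projects to all-zero en-face maps
  z <- project_slabs(array(0, dim = dim(d)), fl, sf)
  expect_true(all(z$SVP$decorr == 0) && all(z$DCP$decorr == 0))
})

test_that("binarization zeroes the border margin and respects the signal gate", {
  set.seed(1)
  dec <- matrix(0, 64, 64)
  dec[30:34, ] <- 0.9 # a horizontal tube
  sig <- matrix(100, 64, 64)
  e <- make_enface(dec, sig)
  m <- binarize_vessels(e, margin = 10L)
  expect_true(all(!m$mask[1:10, ]))
  expect_true(all(!m$mask[, 55:64]))
  expect_true(all(m$excluded[1:10, ]))
  # uniform low signal below the gate gives an empty mask
  weak <- make_enface(dec, matrix(2, 64, 64)) # 2x floor < 10x
  expect_equal(sum(binarize_vessels(weak, margin = 0L)$mask), 0)
})

test_that("a strong phantom tube is recovered with good recall and precision", {
  set.seed(3)
  dec <- matrix(0, 96, 96)
  truth <- matrix(FALSE, 96, 96)
  for (i in 1:96) {
    j <- round(48 + 10 * sin(i / 15))
    truth[i, (j - 2):(j + 2)] <- TRUE
  }
  dec[truth] <- 0.9
  dec <- dec + matrix(abs(rnorm(96 * 96, 0, 0.02)), 96)
  e <- make_enface(dec, matrix(50, 96, 96))
  m <- binarize_vessels(e, margin = 0L)
  eroded <- truth & !retquant:::shift2(!truth, 1, 0) & !retquant:::shift2(!truth, -1, 0) &
    !retquant:::shift2(!truth, 0, 1) & !retquant:::shift2(!truth, 0, -1)
  recall <- sum(m$mask & eroded) / sum(eroded)
  precision <- sum(m$mask & truth) / sum(m$mask)
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
})

test_that("ONH cutout removes exactly the brute-force pixel set", {
  ones <- make_mask(matrix(TRUE, 128, 128), dx = 2, dy = 2, center = c(128, 128))
  cut <- cut_onh(ones, radius_um = 100)
  # brute-force oracle
  n_removed <- 0L
  for (i in 1:128) for (j in 1:128) {
    if (sqrt(((i - 0.5) * 2 - 128)^2 + ((j - 0.5) * 2 - 128)^2) < 100) {
      n_removed <- n_removed + 1L
    }
  }
  expect_equal(sum(!cut$mask), n_removed)
  expect_equal(sum(cut$excluded), n_removed)
  # radius zero is the identity
  expect_equal(cut_onh(ones, radius_um = 0)$mask, ones$mask)
  # corner cutout removes about a quarter disc
  corner <- cut_onh(make_mask(matrix(TRUE, 128, 128), dx = 2, dy = 2),
                    center_um = c(0, 0), radius_um = 100)
  n_corner <- 0L
  for (i in 1:128) for (j in 1:128) {
    if (sqrt(((i - 0.5) * 2)^2 + ((j - 0.5) * 2)^2) < 100) n_corner <- n_corner + 1L
  }
  expect_equal(sum(!corner$mask), n_corner)
})

test_that("SNR sector map zones behave geometrically", {
  sig <- matrix(40, 100, 100)
  e <- make_enface(matrix(0, 100, 100), sig, floor = 2, dx = 10, dy = 10)
  g <- snr_sector_map(e)
  expect_true(all(abs(g$zones$snr - 20) < 1e-9))
  # every pixel belongs to exactly one zone
  expect_equal(sum(g$zones$n_pixels), 100 * 100)
  # max ring index reaching the corners of a centred 1000 um field is 7
  expect_equal(max(g$zones$ring), 7L)
  # radially decaying signal gives non-increasing zone SNR along rings
  co <- retquant:::enface_coords(100, 100, 10, 10)
  dist <- sqrt(outer((co$x - 500)^2, rep(1, 100)) + outer(rep(1, 100), (co$y - 500)^2))
  e2 <- make_enface(matrix(0, 100, 100), 40 * exp(-dist / 400), floor = 2,
                    dx = 10, dy = 10)
  g2 <- snr_sector_map(e2)
  for (q in 0:3) {
    zq <- dplyr::arrange(dplyr::filter(g2$zones, .data$quadrant == q), .data$ring)
    expect_true(all(diff(zq$snr) <= 1e-9))
  }
})

test_that("SNR gating includes and excludes zones per the plexus thresholds", {
  # two radial SNR regimes: inner rings above 20x, outer between 15x and 20x
  co <- retquant:::enface_coords(100, 100, 10, 10)
  dist <- sqrt(outer((co$x - 500)^2, rep(1, 100)) + outer(rep(1, 100), (co$y - 500)^2))
  sig <- ifelse(dist < 300, 50, 17)
  mask <- matrix(rep(c(TRUE, FALSE), 5000), 100, 100) # checkerboard-ish 50%
  e <- make_enface(matrix(0.5, 100, 100), sig, floor = 1, dx = 10, dy = 10)
  g <- snr_sector_map(e)
  vm <- make_mask(mask, dx = 10, dy = 10)
  svp <- gated_vessel_density(vm, g, plexus = "SVP")
  dcp <- gated_vessel_density(vm, g, plexus = "DCP")
  expect_gt(svp$n_zones_excluded, 0)
  # the 15x gate admits every zone the 20x gate admits, and more here
  expect_gt(dcp$n_zones_included, svp$n_zones_included)
  expect_equal(svp$density_pct, 50, tolerance = 1)
  expect_equal(dcp$density_pct, 50, tolerance = 1)
  # all gated out -> missing, not zero
  e_low <- make_enface(matrix(0.5, 100, 100), matrix(3, 100, 100), floor = 1,
                       dx = 10, dy = 10)
  none <- gated_vessel_density(vm, snr_sector_map(e_low), plexus = "SVP")
  expect_true(none$missing)
  expect_true(is.na(none$density_pct))
})

test_that("density counts follow the definition and are quadrant-relabel invariant", {
  mask <- matrix(FALSE, 60, 60)
  mask[1:30, ] <- TRUE
  vm <- make_mask(mask, dx = 10, dy = 10)
  e <- make_enface(matrix(0.5, 60, 60), matrix(100, 60, 60), dx = 10, dy = 10)
  g <- snr_sector_map(e)
  res <- gated_vessel_density(vm, g, plexus = "ICP")
  expect_equal(res$density_pct, 100 * res$n_pos / (res$n_pos + res$n_neg))
  expect_equal(res$density_pct, 50)
  # relabeling quadrants leaves the density unchanged
  g2 <- g; g2$quad <- (g2$quad + 1L) %% 4L
  g2$zones$quadrant <- (g2$zones$quadrant + 1L) %% 4L
  expect_equal(gated_vessel_density(vm, g2, plexus = "ICP")$density_pct, 50)
  # gating is local: forcing distant zones below the gate does not change
  # the included zones' contribution
  sig3 <- matrix(100, 60, 60)
  sig3[, 1:10] <- 1
  e3 <- make_enface(matrix(0.5, 60, 60), sig3, dx = 10, dy = 10)
  g3 <- snr_sector_map(e3)
  res3 <- gated_vessel_density(vm, g3, plexus = "ICP")
  key_all <- g$quad * (max(g$ring) + 1L) + g$ring
  inc3 <- dplyr::filter(g3$zones, !.data$empty, .data$snr >= 20)
  keys3 <- inc3$quadrant * (max(g3$ring) + 1L) + inc3$ring
  sel <- matrix(key_all %in% keys3, 60, 60)
  expect_equal(res3$n_pos, sum(mask & sel))
})
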