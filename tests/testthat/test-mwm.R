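geom <- pool_geometry()

test_that("latency handles contact, no-contact and start-on-platform", {
  # straight path through the platform
  tr <- line_trajectory(c(0.4, -0.4) / sqrt(2), geom$platform_center, 0.1)
  d0 <- sqrt(sum((c(tr$x_m[1], tr$y_m[1]) - geom$platform_center)^2))
  expect_equal(latency(tr, geom), (d0 - geom$platform_radius) / 0.1,
               tolerance = 1 / 14 + 1e-9)
  # never entering the platform
  far <- line_trajectory(c(0.45, 0), c(0.45, 0.001), 0.0001)
  expect_equal(latency(far, geom, cap = 60), 60)
  # first sample already on the platform
  on <- tibble::tibble(t_s = c(0, 1), x_m = rep(geom$platform_center[1], 2),
                       y_m = rep(geom$platform_center[2], 2))
  expect_equal(latency(on, geom), 0)
  expect_error(latency(on[0, ], geom), "empty")
})

test_that("path length matches closed forms for lines and circles", {
  still <- tibble::tibble(t_s = 0:10 / 14, x_m = 0.1, y_m = 0.2)
  expect_equal(path_length(still), 0)
  # unit-speed straight line for 3.6 s
  ln <- line_trajectory(c(-0.45, 0), c(-0.45 + 3.6, 0), 1)
  expect_equal(path_length(ln, truncate_at = 3.6), 3.6, tolerance = 1 / 14)
  # circle: k revolutions within the polygonal shortfall bound
  r <- 0.3; k <- 2; speed <- 0.25
  circ <- circle_trajectory(r, k, speed)
  exact <- 2 * pi * r * k
  step_angle <- speed / (r * 14)
  shortfall <- exact * (1 - sin(step_angle / 2) / (step_angle / 2))
  got <- path_length(circ)
  # the sampled path may overshoot the final revolution by up to one frame
  expect_lte(got, exact + speed / 14 + 1e-9)
  expect_gte(got, exact - shortfall - speed / 14)
})

test_that("floating fraction detects sustained low-speed episodes", {
  expect_equal(floating_fraction(tibble::tibble(t_s = 0:839 / 14, x_m = 0, y_m = 0)),
               100)
  moving <- circle_trajectory(0.3, 2, 0.1)
  expect_equal(floating_fraction(moving), 0)
  # one injected 6 s stationary episode in a 60 s trial
  n <- 840; t <- (0:(n - 1)) / 14
  x <- 0.1 * cos(0.5 * t); y <- 0.1 * sin(0.5 * t)
  hold <- t >= 20 & t < 26
  x[hold] <- x[which(t >= 20)[1]]; y[hold] <- y[which(t >= 20)[1]]
  # re-anchor the path after the hold so speeds stay high elsewhere
  x[t >= 26] <- 0.1 * cos(0.5 * (t[t >= 26] - 6)); y[t >= 26] <- 0.1 * sin(0.5 * (t[t >= 26] - 6))
  frac <- floating_fraction(tibble::tibble(t_s = t, x_m = x, y_m = y))
  expect_equal(frac, 10, tolerance = 1)
})

test_that("thigmotaxis fraction follows the wall-zone geometry", {
  wall <- circle_trajectory(0.48, 1, 0.2)
  expect_equal(thigmotaxis_fraction(wall, geom), 100)
  center <- tibble::tibble(t_s = 0:50 / 14, x_m = 0.01, y_m = 0)
  expect_equal(thigmotaxis_fraction(center, geom), 0)
  # half near the wall, half crossing the center, equal durations
  half1 <- circle_trajectory(0.47, 30 * 0.2 / (2 * pi * 0.47), 0.2)
  half1 <- half1[half1$t_s < 30, ]
  half2 <- tibble::tibble(t_s = seq(30, 59.9, by = 1 / 14), x_m = 0.01, y_m = 0.01)
  tr <- rbind(half1, half2)
  expect_equal(thigmotaxis_fraction(tr, geom), 50, tolerance = 2)
})

test_that("quadrant abidance partitions trial time", {
  circ <- circle_trajectory(0.3, 3, 0.3 * 2 * pi * 3 / 59.9)
  ab <- quadrant_abidance(circ, geom)
  expect_equal(unname(ab), rep(25, 4), tolerance = 1)
  ne <- tibble::tibble(t_s = 0:99 / 14, x_m = 0.2, y_m = 0.2)
  expect_equal(unname(quadrant_abidance(ne, geom)["NE"]), 100)
  set.seed(1)
  rw <- tibble::tibble(t_s = 0:199 / 14,
                       x_m = cumsum(rnorm(200, 0, 0.01)),
                       y_m = cumsum(rnorm(200, 0, 0.01)))
  expect_equal(sum(quadrant_abidance(rw, geom)), 100, tolerance = 1e-9)
})

test_that("target-zone crossings count entry events", {
  # chord passing through the zone twice
  p <- geom$platform_center
  seg <- rbind(
    line_trajectory(p + c(-0.2, 0), p, 0.2),
    line_trajectory(p, p + c(0.2, 0), 0.2),
    line_trajectory(p + c(0.2, 0), p, 0.2)
  )
  seg$t_s <- (seq_len(nrow(seg)) - 1) / 14
  expect_equal(target_zone_crossings(seg, geom), 2)
  never <- circle_trajectory(0.45, 1, 0.3)
  expect_equal(target_zone_crossings(never, geom), 0)
  inside <- tibble::tibble(t_s = 0:10 / 14, x_m = p[1], y_m = p[2])
  expect_equal(target_zone_crossings(inside, geom), 1)
})

test_that("trial_table composes single-trial metrics with the right schema", {
  cfg <- behavior_config(geom = geom)
  sched <- mwm_start_schedule()
  labels <- dplyr::bind_rows(lapply(1:2, function(a) {
    dplyr::mutate(sched, animal = paste0("m", a))
  }))
  trajs <- lapply(seq_len(nrow(labels)), function(i) {
    generate_trajectory(0.5, labels$day[i], labels$trial[i], cfg, seed = i)
  })
  tab <- trial_table(trajs, labels, geom)
  expect_equal(nrow(tab), 2 * 17)
  d5 <- dplyr::filter(tab, .data$day == 5)
  expect_true(all(is.na(d5$latency_s)))
  expect_true(all(!is.na(d5$crossings)))
  expect_true(all(abs(d5$abidance_ne + d5$abidance_nw + d5$abidance_sw +
                        d5$abidance_se - 100) < 0.01))
  tr <- dplyr::filter(tab, .data$day < 5)
  expect_true(all(is.na(tr$crossings)))
  expect_true(all(tr$latency_s <= 60))
  # row metrics reproduce the single-trial operations
  i <- 3
  expect_equal(tab$latency_s[i], latency(trajs[[i]], geom))
  expect_equal(tab$thigmotaxis_pct[i], thigmotaxis_fraction(trajs[[i]], geom))
  # unknown day/trial errors
  bad <- labels; bad$trial[1] <- 9L
  expect_error(trial_table(trajs, bad, geom), "schedule")
})

test_that("metrics are invariant under rigid rotation of path and geometry", {
  cfg <- behavior_config(geom = geom)
  tr <- generate_trajectory(1, day = 5, trial = 1, config = cfg, seed = 4)
  th <- pi / 2
  rot <- tibble::tibble(
    t_s = tr$t_s,
    x_m = cos(th) * tr$x_m - sin(th) * tr$y_m,
    y_m = sin(th) * tr$x_m + cos(th) * tr$y_m
  )
  geom_rot <- pool_geometry(platform_quadrant = "SW") # NW rotated by +90 deg
  expect_equal(target_zone_crossings(rot, geom_rot),
               target_zone_crossings(tr, geom))
  expect_equal(thigmotaxis_fraction(rot, geom_rot),
               thigmotaxis_fraction(tr, geom))
  expect_equal(path_length(rot), path_length(tr), tolerance = 1e-9)
  ab <- quadrant_abidance(tr, geom)
  ab_rot <- quadrant_abidance(rot, geom_rot)
  # +90 degrees maps NE->NW, NW->SW, SW->SE, SE->NE
  expect_equal(unname(ab_rot[c("NW", "SW", "SE", "NE")]),
               unname(ab[c("NE", "NW", "SW", "SE")]), tolerance = 1e-9)
})
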