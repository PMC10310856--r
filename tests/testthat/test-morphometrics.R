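test_that("form factor matches closed forms and is scale invariant", {
  expect_equal(form_factor(pi, 2 * pi), 1)            # circle, r = 1
  expect_equal(form_factor(1, 4), pi / 4)             # unit square
  expect_equal(form_factor(10, 22), 40 * pi / 484)    # 1 x 10 rectangle
  for (s in c(0.1, 2, 50)) {
    expect_equal(form_factor(s^2 * pi, s * 2 * pi), 1)
    expect_equal(form_factor(s^2 * 10, s * 22), 40 * pi / 484)
  }
  expect_error(form_factor(0, 1), "positive")
  expect_error(form_factor(1, -2), "positive")
})

test_that("mask measurement approaches analytic form factors", {
  disk <- make_shape_mask("disk", size_px = 128)
  m <- measure_mask(disk)
  expect_lte(abs(m$form_factor - 1), 0.05)
  expect_equal(m$area, sum(disk))  # pixel-count area at unit pixel size
  expect_equal(m$area, attr(disk, "truth")$area, tolerance = 0.02)
  expect_equal(m$perimeter, attr(disk, "truth")$perimeter, tolerance = 0.02)

  square <- make_shape_mask("square", size_px = 128)
  expect_equal(measure_mask(square)$form_factor, pi / 4, tolerance = 0.05)

  rect <- make_shape_mask("rectangle", size_px = 128)
  expect_equal(measure_mask(rect)$form_factor,
               attr(rect, "truth")$form_factor, tolerance = 0.05)

  # spiky outlines depress FF below the disk's
  star <- make_shape_mask("star", size_px = 128)
  expect_lt(measure_mask(star)$form_factor, m$form_factor)

  # pixel size scales area and perimeter but not FF
  m2 <- measure_mask(disk, pixel_size = 0.1)
  expect_equal(m2$area, m$area * 0.01)
  expect_equal(m2$form_factor, m$form_factor)
})

test_that("raster FF estimates respect the isoperimetric bound direction", {
  # across generated shapes, nothing beats the disk and all stay near or
  # below 1 (small corner bias at low resolution is documented)
  ffs <- vapply(c("disk", "square", "rectangle", "star"), function(k) {
    measure_mask(make_shape_mask(k, size_px = 160))$form_factor
  }, 0)
  expect_true(all(ffs <= 1.02))
  expect_equal(unname(which.max(ffs)), 1)
})

test_that("mask measurement rejects empty or fragmented masks", {
  expect_error(measure_mask(matrix(0, 10, 10)), "empty mask")
  frag <- matrix(0, 20, 20)
  frag[2:5, 2:5] <- 1
  frag[10:14, 10:14] <- 1
  expect_error(measure_mask(frag), "found 2")
})

test_that("particle profiles bin half-open segments from the tip", {
  prof <- particle_density_profile(seq(0.5, 14.5, by = 1), rep(1, 15))
  expect_equal(prof$counts, rep(1L, 15))
  expect_equal(prof$densities, rep(1, 15))

  empty <- particle_density_profile(numeric(0), rep(1, 15))
  expect_equal(empty$densities, rep(0, 15))

  # particles at or beyond the segment end are excluded; bin edges are
  # half-open so a particle at exactly 1.0 um falls in the second bin
  prof2 <- particle_density_profile(c(1.0, 16, 15), rep(1, 15))
  expect_equal(sum(prof2$counts), 1)
  expect_equal(prof2$counts[2], 1L)
  expect_equal(prof2$n_excluded, 2)

  # densities divide counts by per-bin volumes
  prof3 <- particle_density_profile(c(0.5, 0.6, 2.5), c(2, rep(1, 14)))
  expect_equal(prof3$densities[1], 1)   # 2 particles / 2 um^3
  expect_equal(prof3$densities[3], 1)
})

test_that("particle counts are conserved for arbitrary inputs", {
  set.seed(15)
  for (i in 1:5) {
    d <- runif(200, 0, 20)
    prof <- particle_density_profile(d, runif(15, 0.5, 2))
    expect_equal(sum(prof$counts), sum(d < 15))
  }
})

test_that("particle profile validates volumes and bin arithmetic", {
  expect_error(particle_density_profile(1, rep(1, 15), bin_width = 0.4),
               "integer number of bins")
  expect_error(particle_density_profile(1, rep(1, 10)), "15 bin volumes")
  expect_error(particle_density_profile(1, c(-1, rep(1, 14))), "positive")
  expect_error(particle_density_profile(-2, rep(1, 15)), "nonnegative")
})

test_that("volume ratio and area overlap follow their definitions", {
  expect_equal(volume_ratio(0, 10), 0)
  expect_equal(volume_ratio(5, 10), 0.5)
  expect_equal(volume_ratio(7, 7), 1)
  expect_error(volume_ratio(1, 0), "positive")

  a <- matrix(0, 10, 10); a[1:2, 1:5] <- 1    # 10 px
  b <- matrix(0, 10, 10); b[1:2, 1:2] <- 1    # overlap 4 px
  expect_equal(area_overlap_percent(a, a), 100)
  expect_equal(area_overlap_percent(a, b), 40)
  expect_equal(area_overlap_percent(a, matrix(0, 10, 10)), 0)
  expect_error(area_overlap_percent(a, matrix(0, 5, 5)), "dimensions")
  expect_error(area_overlap_percent(matrix(0, 10, 10), a), "no foreground")
})

test_that("area overlap grows monotonically as the second mask fills in", {
  a <- matrix(0, 12, 12); a[3:8, 3:8] <- 1
  b <- matrix(0, 12, 12)
  prev <- 0
  for (col in 3:8) {
    b[3:8, col] <- 1
    cur <- area_overlap_percent(a, b)
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 100)
})

test_that("dispersion factor is tight for gratings and equivariant to rotation", {
  d0 <- dispersion_factor(make_orientation_texture(0, period_px = 8))
  expect_lt(d0$dispersion, 5)
  expect_lt(abs(d0$fitted_mean - 0), 2)

  d30 <- dispersion_factor(make_orientation_texture(30, period_px = 8))
  expect_lt(abs(d30$fitted_mean - 30), 2)
  expect_lt(abs(d30$dispersion - d0$dispersion), 2)

  dm60 <- dispersion_factor(make_orientation_texture(-60, period_px = 8))
  expect_lt(abs(dm60$fitted_mean - (-60)), 2)
})

test_that("white noise yields high dispersion and poor Gaussian fit", {
  set.seed(5)
  noise <- matrix(rnorm(128 * 128), 128, 128)
  d <- dispersion_factor(noise)
  expect_gt(d$dispersion, 30)
  expect_lt(d$goodness, 0.5)
})

test_that("dispersion factor validates the image and roi", {
  expect_error(dispersion_factor(matrix(1, 40, 40)), "flat image")
  img <- make_orientation_texture(10, size_px = 64)
  expect_error(dispersion_factor(img, roi = matrix(TRUE, 3, 3)), "dimensions")
  expect_error(dispersion_factor(img, roi = matrix(FALSE, 64, 64)),
               "empty roi")
  # an roi restricted to a quadrant still recovers the orientation
  roi <- matrix(FALSE, 64, 64); roi[1:32, 1:32] <- TRUE
  expect_lt(abs(dispersion_factor(img, roi)$fitted_mean - 10), 3)
})

test_that("track speeds follow the stepwise and net definitions", {
  straight <- data.frame(x = c(0, 1, 2), y = c(0, 0, 0))
  expect_equal(track_mean_speed(straight, 1), 1)
  expect_equal(track_net_speed(straight, 1), 1)

  still <- data.frame(x = c(1, 1), y = c(2, 2))
  expect_equal(track_mean_speed(still, 1), 0)

  diagonal <- data.frame(x = 0:3, y = 0:3)
  expect_equal(track_mean_speed(diagonal, 1), sqrt(2))

  # a zig-zag has a higher path speed than net speed
  zig <- data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 2, 3))
  expect_gt(track_mean_speed(zig, 1), track_net_speed(zig, 1))
  # halving the frame interval doubles the speed
  expect_equal(track_mean_speed(zig, 0.5), 2 * track_mean_speed(zig, 1))

  expect_error(track_mean_speed(data.frame(x = 1, y = 1), 1), "two points")
  expect_error(track_mean_speed(straight, 0), "positive")
})

test_that("track tables summarize to their generating speed exactly", {
  pt <- make_particles_and_tracks(n_particles = 50, speed = 0.5,
                                  n_frames = 12, n_tracks = 4, rng_seed = 9)
  summ <- track_speed_summary(pt$tracks, pt$truth$frame_interval)
  expect_equal(nrow(summ), 4)
  expect_equal(summ$mean_speed, rep(0.5, 4), tolerance = 1e-12)
  expect_equal(summ$net_speed, rep(0.5, 4), tolerance = 1e-12)

  path <- tempfile(fileext = ".csv")
  utils::write.csv(pt$tracks, path, row.names = FALSE)
  summ2 <- track_speed_summary(path, 1)
  expect_equal(summ2$mean_speed, summ$mean_speed)
})
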