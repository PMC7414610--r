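# Visual-angle calibration, cropping, polar resampling and quadrant
# assignment.

test_that("visual-angle conversion matches the 288 um/degree protocol", {
  expect_equal(deg_to_mm(6), 1.728)
  expect_equal(round_half_away(deg_to_mm(6), 2), 1.73)
  expect_equal(deg_to_mm(0), 0)
  expect_equal(round_half_away(mm_to_deg(1.5), 1), 5.2)
  expect_error(deg_to_mm(-1), "non-negative")
  # round trip to near machine precision
  r <- c(0.3, 1, 4, 5, 6, 11.7)
  expect_equal(mm_to_deg(deg_to_mm(r)), r, tolerance = 1e-12)
  # custom calibration scales linearly
  cal <- angle_calibration(300)
  expect_equal(deg_to_mm(6, cal), 1.8)
})

test_that("raster grid spacings follow from extent and counts", {
  s <- constant_scan(100)
  expect_equal(s$extent_x_mm / s$n_ascans * 1000, 20) # A-scan spacing um
  expect_equal(s$extent_y_mm / s$n_bscans * 1000, 100) # B-scan spacing um
})

test_that("cropping a 12x8 mm scan to 8x8 mm keeps 400 A-scans", {
  s <- constant_scan(100)
  cr <- crop_to_window(s, c(8, 8))
  expect_equal(cr$n_ascans, 400)
  expect_equal(cr$n_bscans, 80)
  expect_equal(cr$extent_x_mm, 8)
  expect_equal(cr$onh_center_mm, c(4, 4))
})

test_that("a full-extent crop window is a no-op with a warning", {
  s <- constant_scan(100)
  expect_warning(cr <- crop_to_window(s, c(12, 8)), "unchanged")
  expect_identical(cr$thickness, s$thickness)
})

test_that("crop windows near an edge are clamped and the shift recorded", {
  s <- scan_from_function(function(x, y) 50 + x, center = c(1, 4))
  cr <- crop_to_window(s, c(8, 8), center_mm = c(1, 4))
  # oracle by direct index arithmetic: want start 1/0.02 - 200 = -150,
  # clamped to 0, so the shift is 150 px * 0.02 mm = 3 mm
  expect_equal(attr(cr, "crop_offset_px")[1], 0)
  expect_equal(attr(cr, "crop_center_shift_mm")[1], 3)
  expect_equal(cr$n_ascans, 400)
  # ONH centre recomputed in the cropped frame: unchanged x since start = 0
  expect_equal(cr$onh_center_mm[1], 1)
  # pixel content is the leftmost 400 columns
  expect_equal(cr$thickness, s$thickness[, 1:400])
})

test_that("ring sampling is exact on constant and affine fields", {
  s <- constant_scan(87.5)
  for (r in c(4, 5, 6)) {
    p <- sample_ring(s, r)
    expect_true(all(p$valid))
    expect_equal(p$value_um, rep(87.5, 360), tolerance = 1e-12)
  }
  # affine field: full-circle mean equals the centre value
  a <- 40; b <- 3; cc <- -2
  s2 <- scan_from_function(function(x, y) a + b * x + cc * y)
  p2 <- sample_ring(s2, 6)
  center_value <- a + b * 6 + cc * 4
  expect_equal(mean(p2$value_um), center_value, tolerance = 1e-9 * center_value)
})

test_that("bilinear interpolation reproduces node values exactly", {
  set.seed(11)
  s <- scan_from_function(function(x, y) 60 + sin(x) * 10 + cos(y) * 5,
                          nx = 40, ny = 30)
  dx <- s$extent_x_mm / s$n_ascans; dy <- s$extent_y_mm / s$n_bscans
  i <- c(0, 7, 39, 12); j <- c(0, 3, 29, 15)
  got <- cprnfl:::bilinear_sample(s, (i + 0.5) * dx, (j + 0.5) * dy)
  expect_true(all(got$valid))
  expect_equal(got$value, s$thickness[cbind(j + 1, i + 1)])
})

test_that("samples become invalid outside the grid or near invalid pixels", {
  s <- constant_scan(100, nx = 60, ny = 40)
  # ring larger than the scan: flagged invalid, no error
  p <- sample_ring(s, 40)
  expect_true(all(!p$valid))
  # poke a hole and verify contamination is local
  s$valid_mask[20, 30] <- FALSE
  hole_x <- (30 - 0.5) * s$extent_x_mm / 60
  hole_y <- (20 - 0.5) * s$extent_y_mm / 40
  near <- cprnfl:::bilinear_sample(s, hole_x + 0.01, hole_y)
  far <- cprnfl:::bilinear_sample(s, hole_x + 1.5, hole_y)
  expect_false(near$valid)
  expect_true(far$valid)
})

test_that("ring sampling matches direct truth evaluation on a phantom", {
  p <- noiseless_params()
  tr <- make_truth(p)
  s <- render_scan(tr, p)
  for (r in c(4, 6)) {
    prof <- sample_ring(s, r)
    direct <- tr$thickness(rep(r, nrow(prof)), prof$theta_deg)
    expect_lt(max(abs(prof$value_um - direct)), 0.5)
  }
})

test_that("annulus means are area-weighted and converge to the polar centroid", {
  s <- constant_scan(42)
  p <- sample_annulus(s, 5, 6)
  expect_equal(stats::weighted.mean(p$value_um, p$weight), 42,
               tolerance = 1e-12)
  # field T = r (um per degree): weighted mean -> analytic centroid radius
  # (fine raster in y so interpolation curvature bias does not mask the
  # radial convergence under test)
  s2 <- scan_from_function(function(x, y)
    mm_to_deg(sqrt((x - 6)^2 + (y - 4)^2)), ny = 400)
  p2 <- sample_annulus(s2, 5, 6, n_r = 200)
  centroid <- (2 / 3) * (6^3 - 5^3) / (6^2 - 5^2)
  expect_equal(stats::weighted.mean(p2$value_um, p2$weight), centroid,
               tolerance = 1e-4)
  # a degenerate annulus collapses to the midpoint ring
  ring <- sample_ring(s2, 5.5)
  thin <- sample_annulus(s2, 5.5 - 1e-6, 5.5 + 1e-6, n_r = 1)
  expect_equal(stats::weighted.mean(thin$value_um, thin$weight),
               mean(ring$value_um), tolerance = 1e-6)
})

test_that("quadrant schemes partition the circle and bin by convention", {
  for (nm in c("equal90", "gdx")) {
    sc <- quadrant_scheme(nm)
    w <- (sc$end_deg - sc$start_deg) %% 360
    expect_equal(sum(w), 360)
  }
  sc <- quadrant_scheme("equal90")
  expect_equal(cprnfl:::quadrant_of(0, sc), "temporal")
  expect_equal(cprnfl:::quadrant_of(90, sc), "superior")
  expect_equal(cprnfl:::quadrant_of(180, sc), "nasal")
  expect_equal(cprnfl:::quadrant_of(270, sc), "inferior")
  # OS profiles carry anatomical angles, so assignment is unchanged
  s_os <- constant_scan(80, laterality = "OS")
  prof <- assign_quadrants(sample_ring(s_os, 6), sc)
  expect_equal(prof$quadrant[prof$theta_deg == 90], "superior")
  expect_equal(prof$quadrant[prof$theta_deg == 0], "temporal")
  # sector sample counts proportional to widths (+/- 1 of expected)
  gdx <- quadrant_scheme("gdx")
  prof2 <- assign_quadrants(sample_ring(constant_scan(80), 6), gdx)
  counts <- table(prof2$quadrant)
  widths <- c(inferior = 120, nasal = 70, superior = 120, temporal = 50)
  expect_true(all(abs(counts[names(widths)] - widths) <= 1))
})

test_that("OS sampling mirrors the temporal/nasal axis in pixel space", {
  # field with a left-right gradient; OD temporal (theta 0) points +x,
  # OS temporal points -x
  f <- function(x, y) 100 + 10 * (x - 6)
  od <- sample_ring(scan_from_function(f, laterality = "OD"), 6)
  os <- sample_ring(scan_from_function(f, laterality = "OS"), 6)
  v_od_t <- od$value_um[od$theta_deg == 0]
  v_os_t <- os$value_um[os$theta_deg == 0]
  expect_gt(v_od_t, 100)
  expect_lt(v_os_t, 100)
  expect_equal(v_od_t - 100, 100 - v_os_t, tolerance = 1e-9)
})

test_that("field rotation and theta offset cancel in quadrant means", {
  phi <- 23
  p0 <- noiseless_params()
  p1 <- noiseless_params(tilt_deg = phi)
  s0 <- render_scan(make_truth(p0), p0)
  s1 <- render_scan(make_truth(p1), p1)
  m0 <- summarize_scan(s0, "ring_6")
  m1 <- summarize_scan(s1, "ring_6", theta_offset_deg = -phi)
  expect_true(all(abs(m0$mean_um - m1$mean_um) < 0.5))
  # without the correction the tilted quadrant means differ materially
  m1_raw <- summarize_scan(s1, "ring_6")
  expect_gt(max(abs(m0$mean_um - m1_raw$mean_um)), 2)
})
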