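# Ground-truth field construction, scan rendering, cohort simulation.

test_that("default truth reproduces the control quadrant means at 6 degrees", {
  tr <- make_truth(phantom_params())
  th <- seq(0, 359.5, by = 0.5)
  v <- tr$thickness(rep(6, length(th)), th)
  q <- cprnfl:::quadrant_of(th, quadrant_scheme("equal90"))
  m <- tapply(v, q, mean)
  expect_true(m[["superior"]] >= 104 && m[["superior"]] <= 108)
  expect_equal(as.numeric(m[c("temporal", "nasal", "superior", "inferior")]),
               c(61, 65, 106, 105), tolerance = 2 / 61)
  # mean ordering of the double-hump profile
  expect_true(m[["inferior"]] > m[["nasal"]] && m[["superior"]] > m[["nasal"]])
  expect_gt(m[["nasal"]], m[["temporal"]])
})

test_that("truth is periodic, nonnegative, and zero inside the disc", {
  tr <- make_truth(phantom_params())
  th <- runif(50, -720, 720)
  expect_equal(tr$thickness(rep(5, 50), th), tr$thickness(rep(5, 50), th + 360))
  expect_true(all(tr$thickness(runif(100, 0, 12), runif(100, 0, 360)) >= 0))
  expect_equal(tr$thickness(c(0, 0.5, 0.94), c(0, 90, 311)), c(0, 0, 0))
  expect_true(all(tr$thickness(c(0.96, 2, 6), c(10, 100, 200)) > 0))
})

test_that("degenerate shape parameters give a constant field", {
  p <- phantom_params(base_temporal_um = 77, base_nasal_um = 77,
                      peak_superior_um = 0, peak_inferior_um = 0,
                      radial_decay_per_deg = 0)
  tr <- make_truth(p)
  v <- tr$thickness(runif(200, 1, 10), runif(200, 0, 360))
  expect_equal(v, rep(77, 200))
})

test_that("glaucoma factor scales every quadrant mean multiplicatively", {
  th <- seq(0, 359, by = 1)
  v1 <- make_truth(phantom_params())$thickness(rep(6, 360), th)
  v08 <- make_truth(phantom_params(glaucoma_factor = 0.8))$thickness(
    rep(6, 360), th)
  expect_equal(v08, 0.8 * v1, tolerance = 1e-12)
})

test_that("disc radius of 4 degrees or more is rejected", {
  expect_error(phantom_params(disc_radius_deg = 4), "inside the disc")
  expect_error(phantom_params(glaucoma_factor = 0), "glaucoma_factor")
  expect_error(phantom_params(sigma_scan_um = -1), "sigma_scan_um")
})

test_that("a noiseless render equals the truth sampled on the grid", {
  p <- noiseless_params(grid_n_ascans = 120, grid_n_bscans = 60)
  tr <- make_truth(p)
  s <- render_scan(tr, p)
  xs <- (seq_len(120) - 0.5) * (12 / 120)
  ys <- (seq_len(60) - 0.5) * (8 / 60)
  X <- matrix(xs, 60, 120, byrow = TRUE); Y <- matrix(ys, 60, 120)
  r <- mm_to_deg(sqrt((X - 6)^2 + (Y - 4)^2))
  th <- (atan2(4 - Y, X - 6) * 180 / pi) %% 360
  expected <- tr$thickness(r, th)
  inside <- r < p$disc_radius_deg
  expect_equal(s$thickness[!inside], expected[!inside])
  expect_true(all(s$thickness[inside] == 0))
  expect_equal(s$valid_mask, !inside)
})

test_that("pixel-noise SD scales as 1/quality", {
  p0 <- noiseless_params(grid_n_ascans = 500, grid_n_bscans = 250)
  p5 <- noiseless_params(grid_n_ascans = 500, grid_n_bscans = 250,
                         sigma_pixel_um = 5)
  tr <- make_truth(p0)
  base <- render_scan(tr, p0)
  hi <- render_scan(tr, p5, scan_id = "H", quality = 1.0)
  lo <- render_scan(tr, p5, scan_id = "L", quality = 0.5)
  ok <- base$valid_mask & base$thickness > 25 # avoid the clamp at 0
  sd_hi <- sd(hi$thickness[ok] - base$thickness[ok])
  sd_lo <- sd(lo$thickness[ok] - base$thickness[ok])
  expect_equal(sd_lo / sd_hi, 2, tolerance = 0.05)
  expect_equal(sd_hi, 5, tolerance = 0.05 * 5)
})

test_that("forced quadrant loss masks exactly one quadrant", {
  p <- noiseless_params(missing_quadrant_prob = 1)
  tr <- make_truth(p)
  s <- render_scan(tr, p, "sx", "S2", "A1")
  sm <- summarize_scan(s, "ring_6")
  expect_equal(sum(!sm$captured), 1)
  expect_equal(sum(sm$captured), 3)
  # and the mask hole is a full 90-degree sector
  lost <- sm$quadrant[!sm$captured]
  prof <- assign_quadrants(sample_ring(s, 6), quadrant_scheme("equal90"))
  expect_true(all(!prof$valid[prof$quadrant == lost]))
  # neighbouring quadrants stay valid except where interpolation touches
  # masked boundary pixels
  expect_gt(mean(prof$valid[prof$quadrant != lost]), 0.95)
})

test_that("cohort designs produce the right scans and pairing structure", {
  p <- phantom_params(grid_n_ascans = 36, grid_n_bscans = 24,
                      missing_quadrant_prob = 0)
  sc <- simulate_cohort(p, 5, "test_retest", seed = 9)
  expect_length(sc, 10)
  expect_equal(unique(vapply(sc, `[[`, "", "assessor_id")), "A1")
  expect_setequal(vapply(sc, `[[`, "", "scan_id"), c("S1", "S2"))
  q <- vapply(sc, `[[`, 0, "quality")
  expect_equal(sort(unique(q)), c(p$quality_low, p$quality_high))
  ia <- simulate_cohort(p, 5, "interassessor", seed = 9)
  expect_length(ia, 10)
  expect_setequal(vapply(ia, `[[`, "", "assessor_id"), c("A1", "A2"))
  expect_equal(unique(vapply(ia, `[[`, "", "scan_id")), "S1")
  # interassessor arms share acquisition, differ only by assessor offset
  d <- ia[[2]]$thickness - ia[[1]]$thickness
  pos <- d[ia[[1]]$valid_mask & ia[[1]]$thickness > 10 &
             ia[[2]]$thickness > 10]
  expect_lt(sd(pos), 1e-9)
  expect_length(simulate_cohort(p, 0, "test_retest"), 0)
})

test_that("cohorts are reproducible and extensible under a fixed seed", {
  p <- phantom_params(grid_n_ascans = 36, grid_n_bscans = 24)
  a <- simulate_cohort(p, 4, "test_retest", seed = 123)
  b <- simulate_cohort(p, 4, "test_retest", seed = 123)
  expect_identical(a, b)
  # adding subjects never reshuffles existing ones
  big <- simulate_cohort(p, 6, "test_retest", seed = 123)
  expect_identical(a, big[1:8])
  # a different seed changes the data
  cset <- simulate_cohort(p, 4, "test_retest", seed = 124)
  expect_false(identical(a, cset))
})

test_that("subject/scan offsets realise the set variance components", {
  # with zero pixel noise the quadrant mean decomposes exactly into
  # truth + subject + scan offsets; check empirical SDs over a cohort
  p <- phantom_params(grid_n_ascans = 36, grid_n_bscans = 24,
                      sigma_subject_um = 12, sigma_scan_um = 4,
                      sigma_assessor_um = 0, sigma_pixel_um = 0,
                      missing_quadrant_prob = 0)
  sc <- simulate_cohort(p, 300, "test_retest", seed = 77)
  sm <- summaries_at(sc, "ring_6", n_theta = 36)
  pr <- build_pairs(assign_arms(sm, "test_retest"))
  nas <- pr[pr$quadrant == "nasal", ]
  d <- nas$value_a_um - nas$value_b_um     # = scan1 - scan2 offsets
  s <- (nas$value_a_um + nas$value_b_um) / 2
  expect_equal(sd(d) / sqrt(2), 4, tolerance = 0.15)
  expect_equal(sd(s), sqrt(12^2 + 4^2 / 2), tolerance = 0.15)
})
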