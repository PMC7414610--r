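# Synthetic retinal phantom: smooth ground-truth cpRNFL fields plus a
# renderer that adds subject / scan / assessor variance components and
# quality-dependent pixel noise, so the reliability pipeline can be
# exercised and calibrated without patient data.

#' Phantom generator parameters
#'
#' Defaults emulate a hand-held OCT acquisition of a healthy infant eye:
#' a 12 x 8 mm raster of 600 A-scans x 80 B-scans (20 um / 100 um
#' spacing), and an RNFL field whose equal90 quadrant means on the
#' 6-degree ring are approximately temporal 61, nasal 65, superior 106,
#' inferior 105 um — typical control values at that eccentricity. The
#' base/peak amplitudes were obtained by solving the linear system that
#' maps the four shape parameters to the four 6-degree quadrant means.
#'
#' @param grid_n_ascans,grid_n_bscans raster dimensions.
#' @param extent_x_mm,extent_y_mm physical scan extent in mm.
#' @param disc_radius_deg optic-disc radius in visual-angle degrees; the
#'   field is 0 (and masked) inside the disc. Must be < 4 degrees so the
#'   innermost measurement ring stays outside the disc.
#' @param base_temporal_um,base_nasal_um smooth angular baseline levels at
#'   the temporal (0 deg) and nasal (180 deg) poles.
#' @param peak_superior_um,peak_inferior_um amplitudes of the raised-cosine
#'   fiber-bundle bumps centred at 90 and 270 deg (half-width 60 deg).
#' @param radial_decay_per_deg fractional thinning per degree of
#'   eccentricity beyond 4 degrees: `decay(r) = 1 / (1 + d * (r - 4))`.
#' @param glaucoma_factor multiplicative global thinning in (0, 1];
#'   1 = control, < 1 = glaucomatous thinning.
#' @param sigma_subject_um,sigma_scan_um,sigma_assessor_um SDs (um) of the
#'   additive between-subject, within-subject test-retest, and assessor
#'   offsets.
#' @param sigma_pixel_um SD (um) of independent per-pixel noise at
#'   quality 1; the effective SD is `sigma_pixel_um / quality`.
#' @param pixel_noise_ref_deg optional reference eccentricity: when set,
#'   pixel-noise SD additionally scales as `ref / r` so noise decreases
#'   with distance from the disc (NA = spatially uniform noise).
#' @param quality_high,quality_low quality indices in (0, 1] used for the
#'   two arms of a test-retest cohort.
#' @param tilt_deg in-plane rotation of the scan frame about the ONH.
#' @param missing_quadrant_prob probability that a rendered scan loses one
#'   full quadrant (masked invalid).
#' @param seed default master RNG seed.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(grid_n_ascans = 600, grid_n_bscans = 80,
                           extent_x_mm = 12, extent_y_mm = 8,
                           disc_radius_deg = 0.95,
                           base_temporal_um = 65.63, base_nasal_um = 70.52,
                           peak_superior_um = 74.65, peak_inferior_um = 72.96,
                           radial_decay_per_deg = 0.05,
                           glaucoma_factor = 1,
                           sigma_subject_um = 12, sigma_scan_um = 4,
                           sigma_assessor_um = 2, sigma_pixel_um = 5,
                           pixel_noise_ref_deg = NA_real_,
                           quality_high = 1, quality_low = 0.5,
                           tilt_deg = 0, missing_quadrant_prob = 0.12,
                           seed = 42) {
  p <- list(grid_n_ascans = grid_n_ascans, grid_n_bscans = grid_n_bscans,
            extent_x_mm = extent_x_mm, extent_y_mm = extent_y_mm,
            disc_radius_deg = disc_radius_deg,
            base_temporal_um = base_temporal_um, base_nasal_um = base_nasal_um,
            peak_superior_um = peak_superior_um,
            peak_inferior_um = peak_inferior_um,
            radial_decay_per_deg = radial_decay_per_deg,
            glaucoma_factor = glaucoma_factor,
            sigma_subject_um = sigma_subject_um, sigma_scan_um = sigma_scan_um,
            sigma_assessor_um = sigma_assessor_um,
            sigma_pixel_um = sigma_pixel_um,
            pixel_noise_ref_deg = pixel_noise_ref_deg,
            quality_high = quality_high, quality_low = quality_low,
            tilt_deg = tilt_deg, missing_quadrant_prob = missing_quadrant_prob,
            seed = seed)
  for (nm in c("sigma_subject_um", "sigma_scan_um", "sigma_assessor_um",
               "sigma_pixel_um"))
    stop_if_not_scalar_num(p[[nm]], nm, lower = 0)
  stop_if_not_scalar_num(glaucoma_factor, "glaucoma_factor",
                         lower = 1e-12, upper = 1)
  stop_if_not_scalar_num(quality_high, "quality_high", lower = 1e-12, upper = 1)
  stop_if_not_scalar_num(quality_low, "quality_low", lower = 1e-12, upper = 1)
  stop_if_not_scalar_num(missing_quadrant_prob, "missing_quadrant_prob",
                         lower = 0, upper = 1)
  stop_if_not_scalar_num(disc_radius_deg, "disc_radius_deg", lower = 1e-12)
  stop_if_not_scalar_num(radial_decay_per_deg, "radial_decay_per_deg",
                         lower = 0)
  if (disc_radius_deg >= 4)
    stop("disc_radius_deg must be < 4 degrees: the innermost ring would fall inside the disc")
  class(p) <- "phantom_params"
  p
}

# Raised cosine bump of half-width 60 deg centred at `center` (wrapped).
raised_cosine <- function(theta_deg, center, half_width = 60) {
  d <- (theta_deg - center + 180) %% 360 - 180
  0.5 * (1 + cos(pi * pmin(abs(d) / half_width, 1)))
}

#' Build a ground-truth RNFL field
#'
#' The field is separable in polar coordinates about the disc centre:
#' `T(r, theta) = g * [base(theta) + peaks(theta)] * decay(r)`, where
#' `base` interpolates the temporal and nasal baseline levels with a
#' cosine ramp, `peaks` are two raised-cosine bumps in the superior and
#' inferior sectors (the double-hump TSNIT profile), `decay` is a gentle
#' hyperbolic thinning with eccentricity anchored at 4 degrees, and
#' `g` is the glaucoma thinning factor. The field is exactly 0 inside the
#' optic disc; `decay` is evaluated with `r` clamped at the disc edge.
#'
#' @param params a [phantom_params()].
#' @return A `ground_truth_field` with elements `thickness(r_deg,
#'   theta_deg)` (vectorised), `onh_center_mm`, `laterality`, `params`.
#' @export
make_truth <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  thick <- function(r_deg, theta_deg) {
    base <- p$base_temporal_um +
      (p$base_nasal_um - p$base_temporal_um) * (1 - cos(theta_deg * pi / 180)) / 2
    peaks <- p$peak_superior_um * raised_cosine(theta_deg, 90) +
             p$peak_inferior_um * raised_cosine(theta_deg, 270)
    r_eff <- pmax(r_deg, p$disc_radius_deg)
    decay <- 1 / (1 + p$radial_decay_per_deg * (r_eff - 4))
    p$glaucoma_factor * (base + peaks) * decay *
      (r_deg >= p$disc_radius_deg)
  }
  structure(list(thickness = thick,
                 onh_center_mm = c(p$extent_x_mm / 2, p$extent_y_mm / 2),
                 laterality = "OD", params = p),
            class = "ground_truth_field")
}

# Polar coordinates (r in visual degrees, anatomical TSNIT theta in deg)
# of physical points, given centre, laterality and a frame tilt: a pixel
# at frame angle phi carries anatomy from angle phi + tilt.
pixel_polar <- function(x, y, center_mm, laterality, tilt_deg, cal) {
  sx <- if (laterality == "OS") -1 else 1
  ex <- sx * (x - center_mm[1])
  ey <- center_mm[2] - y
  r_deg <- mm_to_deg(sqrt(ex^2 + ey^2), cal)
  theta <- (atan2(ey, ex) * 180 / pi + tilt_deg) %% 360
  list(r_deg = r_deg, theta_deg = theta)
}

#' Render a noisy raster scan from a ground-truth field
#'
#' Samples the truth on the raster grid, then adds the additive variance
#' components: a subject offset (shared by all scans of a subject), a
#' scan offset (per acquisition), an assessor offset (per segmentation)
#' and independent per-pixel noise with SD `sigma_pixel_um / quality`
#' (optionally scaled by `ref/r`, see [phantom_params()]). Each offset is
#' drawn from its own RNG stream keyed by `(seed, subject_id, ...)` via
#' [derive_seed()], so cohorts are reproducible and extensible. A full
#' quadrant is masked invalid with probability `missing_quadrant_prob`.
#' Thickness is clamped at 0; pixels inside the disc are 0 and invalid.
#'
#' @param truth a [make_truth()] field.
#' @param params a [phantom_params()].
#' @param subject_id,scan_id,assessor_id labels keying the RNG streams.
#' @param quality quality index in (0, 1].
#' @param missing_quadrant_prob override of `params$missing_quadrant_prob`
#'   (cohort designs disable masking on first scans).
#' @param cal an [angle_calibration()].
#' @return A [raster_scan()].
#' @export
render_scan <- function(truth, params = truth$params,
                        subject_id = "subj", scan_id = "scan",
                        assessor_id = "assessor",
                        quality = params$quality_high,
                        missing_quadrant_prob = params$missing_quadrant_prob,
                        cal = angle_calibration()) {
  p <- params
  nx <- p$grid_n_ascans; ny <- p$grid_n_bscans
  dx <- p$extent_x_mm / nx; dy <- p$extent_y_mm / ny
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dy
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  pol <- pixel_polar(X, Y, truth$onh_center_mm, truth$laterality,
                     p$tilt_deg, cal)
  tval <- truth$thickness(pol$r_deg, pol$theta_deg)

  off_subject <- if (p$sigma_subject_um > 0)
    with_seed(derive_seed(p$seed, "subject", subject_id),
              stats::rnorm(1, 0, p$sigma_subject_um)) else 0
  off_scan <- if (p$sigma_scan_um > 0)
    with_seed(derive_seed(p$seed, "scan", subject_id, scan_id),
              stats::rnorm(1, 0, p$sigma_scan_um)) else 0
  off_assessor <- if (p$sigma_assessor_um > 0)
    with_seed(derive_seed(p$seed, "assessor", subject_id, scan_id, assessor_id),
              stats::rnorm(1, 0, p$sigma_assessor_um)) else 0

  inside_disc <- pol$r_deg < p$disc_radius_deg
  val <- tval + off_subject + off_scan + off_assessor
  if (p$sigma_pixel_um > 0) {
    sd_px <- p$sigma_pixel_um / quality
    # keyed by acquisition only: two assessors segmenting the same scan
    # see identical pixel noise, differing only in their offsets
    noise <- with_seed(
      derive_seed(p$seed, "pixels", subject_id, scan_id),
      stats::rnorm(nx * ny))
    noise <- matrix(noise, ny, nx)
    if (is.finite(p$pixel_noise_ref_deg)) {
      scale_r <- p$pixel_noise_ref_deg /
        pmax(pol$r_deg, p$disc_radius_deg)
      noise <- noise * scale_r
    }
    val <- val + sd_px * noise
  }
  val <- pmax(val, 0)
  val[inside_disc] <- 0
  mask <- !inside_disc

  if (missing_quadrant_prob > 0) {
    draws <- with_seed(derive_seed(p$seed, "missing", subject_id, scan_id),
                       stats::runif(2))
    if (draws[1] < missing_quadrant_prob) {
      scheme <- quadrant_scheme("equal90")
      qd <- scheme$quadrant[ceiling(draws[2] * 4)]
      qpix <- quadrant_of(pol$theta_deg, scheme) == qd
      mask[qpix] <- FALSE
    }
  }
  val[!mask] <- 0

  raster_scan(thickness = val, valid_mask = mask,
              extent_x_mm = p$extent_x_mm, extent_y_mm = p$extent_y_mm,
              onh_center_mm = truth$onh_center_mm,
              laterality = truth$laterality, quality = quality,
              subject_id = subject_id, scan_id = scan_id,
              assessor_id = assessor_id)
}

#' Simulate a paired-measurement cohort
#'
#' `design = "test_retest"`: two consecutive scans per subject, scan `S1`
#' acquired at `quality_high` and scan `S2` at `quality_low`, independent
#' scan offsets, the same assessor (`A1`); quadrant loss can only affect
#' the second scan (first scans are assumed complete, as when an examiner
#' re-acquires until the first scan is usable). `design =
#' "interassessor"`: one underlying scan (`S1`, high quality) per subject
#' segmented twice, by `A1` and `A2`, with independent assessor offsets
#' and identical acquisition noise.
#'
#' @param params a [phantom_params()].
#' @param n_subjects number of subjects.
#' @param design `"test_retest"` or `"interassessor"`.
#' @param seed master seed; defaults to `params$seed`.
#' @return A list of `2 * n_subjects` [raster_scan()] objects.
#' @export
simulate_cohort <- function(params = phantom_params(), n_subjects,
                            design = c("test_retest", "interassessor"),
                            seed = params$seed) {
  design <- match.arg(design)
  p <- params
  p$seed <- seed
  truth <- make_truth(p)
  scans <- vector("list", 2L * n_subjects)
  if (n_subjects == 0) return(scans)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("subj%03d", i)
    if (design == "test_retest") {
      a <- render_scan(truth, p, sid, "S1", "A1", quality = p$quality_high,
                       missing_quadrant_prob = 0)
      b <- render_scan(truth, p, sid, "S2", "A1", quality = p$quality_low)
    } else {
      a <- render_scan(truth, p, sid, "S1", "A1", quality = p$quality_high,
                       missing_quadrant_prob = 0)
      b <- render_scan(truth, p, sid, "S1", "A2", quality = p$quality_high,
                       missing_quadrant_prob = 0)
      b$scan_id <- "S1"
    }
    scans[[2 * i - 1]] <- a
    scans[[2 * i]] <- b
  }
  scans
}
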