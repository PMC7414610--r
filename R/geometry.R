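# Coordinate conventions, visual-angle calibration, cropping and polar
# resampling on the anisotropic raster grid.
#
# Conventions used throughout the package:
#  * Scan frame: x to the right along the A-scan (fast) axis, y downward
#    along the B-scan (slow) axis, origin at the top-left corner of the
#    scan; the centre of pixel (row j, col i), 0-based, sits at
#    ((i + 0.5) * dx, (j + 0.5) * dy) mm.
#  * Angles: TSNIT frame, theta = 0 deg temporal, 90 superior, 180 nasal,
#    270 inferior, for the right-eye (OD) anatomy. Superior is "up"
#    (decreasing y). Left-eye (OS) scans are mirrored about the vertical
#    axis at sampling time so reported angles are always anatomical.

#' Visual-angle calibration
#'
#' Lateral distance on the retina per degree of visual angle. The
#' hand-held OCT default is 288 um/degree for the adult-eye setting.
#'
#' @param um_per_degree micrometres of retina per degree of visual angle.
#' @return An object of class `angle_calibration`.
#' @export
angle_calibration <- function(um_per_degree = 288) {
  stop_if_not_scalar_num(um_per_degree, "um_per_degree", lower = 1e-9)
  structure(list(um_per_degree = um_per_degree), class = "angle_calibration")
}

#' Convert visual-angle degrees to lateral millimetres
#'
#' @param r_deg eccentricity in degrees (non-negative).
#' @param cal an [angle_calibration()].
#' @return Lateral distance in mm.
#' @export
deg_to_mm <- function(r_deg, cal = angle_calibration()) {
  if (any(r_deg < 0)) stop("visual-angle radius must be non-negative")
  r_deg * cal$um_per_degree / 1000
}

#' Convert lateral millimetres to visual-angle degrees
#'
#' @param r_mm lateral distance in mm (non-negative).
#' @inheritParams deg_to_mm
#' @return Eccentricity in degrees.
#' @export
mm_to_deg <- function(r_mm, cal = angle_calibration()) {
  if (any(r_mm < 0)) stop("lateral distance must be non-negative")
  r_mm * 1000 / cal$um_per_degree
}

#' Construct a raster thickness scan
#'
#' Container for a segmented RNFL thickness map on the scanner's raster
#' grid (rows = B-scans, columns = A-scans) together with the physical and
#' administrative metadata the analysis needs.
#'
#' @param thickness numeric matrix of thickness values in um,
#'   `n_bscans x n_ascans`.
#' @param valid_mask logical matrix of the same shape; `TRUE` where the
#'   thickness value is usable. Defaults to everything valid.
#' @param extent_x_mm,extent_y_mm physical width and height of the scan.
#' @param onh_center_mm optic-nerve-head centre `(x, y)` in mm, scan frame.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param quality scanner quality index in (0, 1].
#' @param subject_id,scan_id,assessor_id labels.
#' @return An object of class `raster_scan`.
#' @export
raster_scan <- function(thickness, valid_mask = NULL,
                        extent_x_mm, extent_y_mm, onh_center_mm,
                        laterality = c("OD", "OS"), quality = 1,
                        subject_id = "subj", scan_id = "scan",
                        assessor_id = "assessor") {
  laterality <- match.arg(laterality)
  if (!is.matrix(thickness)) stop("'thickness' must be a matrix")
  if (is.null(valid_mask)) valid_mask <- !is.na(thickness)
  if (!identical(dim(valid_mask), dim(thickness)))
    stop("'valid_mask' must have the shape of 'thickness'")
  stop_if_not_scalar_num(extent_x_mm, "extent_x_mm", lower = 1e-9)
  stop_if_not_scalar_num(extent_y_mm, "extent_y_mm", lower = 1e-9)
  if (length(onh_center_mm) != 2L || any(!is.finite(onh_center_mm)))
    stop("'onh_center_mm' must be numeric (x, y)")
  if (onh_center_mm[1] < 0 || onh_center_mm[1] > extent_x_mm ||
      onh_center_mm[2] < 0 || onh_center_mm[2] > extent_y_mm)
    stop("'onh_center_mm' must lie inside the scan extent")
  stop_if_not_scalar_num(quality, "quality", lower = 1e-12, upper = 1)
  if (any(thickness[valid_mask] < 0, na.rm = TRUE))
    stop("valid thickness values must be non-negative")
  structure(list(
    thickness = thickness, valid_mask = valid_mask,
    n_ascans = ncol(thickness), n_bscans = nrow(thickness),
    extent_x_mm = extent_x_mm, extent_y_mm = extent_y_mm,
    onh_center_mm = as.numeric(onh_center_mm), laterality = laterality,
    quality = quality, subject_id = subject_id, scan_id = scan_id,
    assessor_id = assessor_id
  ), class = "raster_scan")
}

#' @export
print.raster_scan <- function(x, ...) {
  cat(sprintf(
    "<raster_scan> %s/%s/%s  %d x %d px (%.3g x %.3g mm), %s, quality %.2f\n",
    x$subject_id, x$scan_id, x$assessor_id, x$n_bscans, x$n_ascans,
    x$extent_x_mm, x$extent_y_mm, x$laterality, x$quality))
  cat(sprintf("  ONH centre (%.3f, %.3f) mm; %.1f%% valid\n",
              x$onh_center_mm[1], x$onh_center_mm[2],
              100 * mean(x$valid_mask)))
  invisible(x)
}

ascan_spacing_mm <- function(scan) scan$extent_x_mm / scan$n_ascans
bscan_spacing_mm <- function(scan) scan$extent_y_mm / scan$n_bscans

#' Crop a scan to a window centred on the optic nerve head
#'
#' Reduces the raster to a `w x h` mm window centred on the requested
#' point (by default the ONH centre), in whole-pixel steps. If the window
#' would overhang a scan edge, its position is clamped so it stays inside
#' the source and the applied centre offset is recorded. A 12 x 8 mm,
#' 600 x 80 scan cropped to 8 x 8 mm keeps 400 A-scans.
#'
#' @param scan a [raster_scan()].
#' @param window_mm numeric `(w, h)` window size in mm.
#' @param center_mm window centre in mm; defaults to the ONH centre.
#' @return The cropped `raster_scan`, with `onh_center_mm` recomputed in
#'   the cropped frame and attributes `crop_offset_px` (applied start
#'   indices) and `crop_center_shift_mm` (clamping shift).
#' @export
crop_to_window <- function(scan, window_mm = c(8, 8),
                           center_mm = scan$onh_center_mm) {
  w <- window_mm[1]; h <- window_mm[2]
  dx <- ascan_spacing_mm(scan); dy <- bscan_spacing_mm(scan)
  if (w >= scan$extent_x_mm && h >= scan$extent_y_mm) {
    warning("crop window covers the full scan in both axes; returning scan unchanged")
    return(scan)
  }
  crop_axis <- function(size_mm, extent_mm, n, spacing, c_mm) {
    if (size_mm >= extent_mm) return(list(start = 0L, n = n, shift = 0))
    n_new <- round(size_mm / spacing)
    start <- round(c_mm / spacing - n_new / 2)
    start_cl <- min(max(start, 0L), n - n_new)
    list(start = as.integer(start_cl), n = as.integer(n_new),
         shift = (start_cl - start) * spacing)
  }
  ax <- crop_axis(w, scan$extent_x_mm, scan$n_ascans, dx, center_mm[1])
  ay <- crop_axis(h, scan$extent_y_mm, scan$n_bscans, dy, center_mm[2])
  cols <- (ax$start + 1L):(ax$start + ax$n)
  rows <- (ay$start + 1L):(ay$start + ay$n)
  out <- raster_scan(
    thickness = scan$thickness[rows, cols, drop = FALSE],
    valid_mask = scan$valid_mask[rows, cols, drop = FALSE],
    extent_x_mm = ax$n * dx, extent_y_mm = ay$n * dy,
    onh_center_mm = c(scan$onh_center_mm[1] - ax$start * dx,
                      scan$onh_center_mm[2] - ay$start * dy),
    laterality = scan$laterality, quality = scan$quality,
    subject_id = scan$subject_id, scan_id = scan$scan_id,
    assessor_id = scan$assessor_id)
  attr(out, "crop_offset_px") <- c(ax$start, ay$start)
  attr(out, "crop_center_shift_mm") <- c(ax$shift, ay$shift)
  out
}

# Bilinear interpolation at physical positions (xs, ys) in mm, respecting
# the anisotropic pixel spacing. No extrapolation beyond the hull of pixel
# centres. Returns value and validity (a sample is invalid if any node
# with non-zero weight is invalid, or the position leaves the grid).
bilinear_sample <- function(scan, xs, ys) {
  dx <- ascan_spacing_mm(scan); dy <- bscan_spacing_mm(scan)
  gx <- xs / dx - 0.5
  gy <- ys / dy - 0.5
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0;   fy <- gy - j0
  # snap to the node when within float tolerance of it, then collapse
  # zero-weight neighbours so exact node positions need only one node
  snap <- function(f, i) {
    hi <- f > 1 - 1e-9
    i[hi] <- i[hi] + 1
    f[hi] <- 0
    f[f < 1e-9] <- 0
    list(f = f, i = i)
  }
  sx <- snap(fx, i0); fx <- sx$f; i0 <- sx$i
  sy <- snap(fy, j0); fy <- sy$f; j0 <- sy$i
  i1 <- i0 + (fx > 0)
  j1 <- j0 + (fy > 0)
  nc <- scan$n_ascans; nr <- scan$n_bscans
  inside <- i0 >= 0 & i1 <= nc - 1 & j0 >= 0 & j1 <= nr - 1
  value <- rep(NA_real_, length(xs))
  valid <- rep(FALSE, length(xs))
  if (any(inside)) {
    i0i <- i0[inside]; i1i <- i1[inside]
    j0i <- j0[inside]; j1i <- j1[inside]
    fxi <- fx[inside]; fyi <- fy[inside]
    th <- scan$thickness; vm <- scan$valid_mask
    idx <- function(j, i) j + 1 + i * nr  # column-major linear index
    v00 <- th[idx(j0i, i0i)]; v10 <- th[idx(j0i, i1i)]
    v01 <- th[idx(j1i, i0i)]; v11 <- th[idx(j1i, i1i)]
    m <- vm[idx(j0i, i0i)] & vm[idx(j0i, i1i)] &
         vm[idx(j1i, i0i)] & vm[idx(j1i, i1i)]
    w00 <- (1 - fxi) * (1 - fyi); w10 <- fxi * (1 - fyi)
    w01 <- (1 - fxi) * fyi;       w11 <- fxi * fyi
    v <- w00 * v00 + w10 * v10 + w01 * v01 + w11 * v11
    value[inside] <- v
    valid[inside] <- m & is.finite(v)
  }
  list(value = value, valid = valid)
}

# Map anatomical TSNIT angles (deg) at eccentricity r_mm to scan-frame
# positions, honouring laterality (OS mirrored about the vertical axis).
tsnit_to_xy <- function(theta_deg, r_mm, center_mm, laterality) {
  th <- theta_deg * pi / 180
  sx <- if (laterality == "OS") -1 else 1
  list(x = center_mm[1] + sx * r_mm * cos(th),
       y = center_mm[2] - r_mm * sin(th))
}

new_cp_profile <- function(df, location) {
  attr(df, "location") <- location
  class(df) <- c("cp_profile", class(df))
  df
}

#' Sample a circumpapillary ring
#'
#' Samples the thickness map along a circle of visual-angle radius
#' `r_deg` centred on the ONH, by bilinear interpolation in physical
#' coordinates. Reported angles are anatomical TSNIT angles; for OS scans
#' the sampling positions are mirrored about the vertical axis so
#' temporal/nasal stay anatomically correct.
#'
#' `theta_offset_deg` is a frame-rotation correction: sampling positions
#' are taken at `theta + theta_offset_deg` in the scan frame while the
#' reported (and quadrant-assigned) angle remains `theta`. Passing the
#' negative of a known scan tilt therefore undoes it.
#'
#' @param scan a [raster_scan()].
#' @param r_deg ring radius in visual-angle degrees (> 0).
#' @param cal an [angle_calibration()].
#' @param n_theta number of evenly spaced samples (>= 4).
#' @param theta_offset_deg scan-frame rotation correction in degrees.
#' @return A `cp_profile` data frame with columns `theta_deg`, `r_deg`,
#'   `value_um`, `valid`, `weight`.
#' @export
sample_ring <- function(scan, r_deg, cal = angle_calibration(),
                        n_theta = 360, theta_offset_deg = 0) {
  s <- ring_core(scan, r_deg, cal, n_theta, theta_offset_deg)
  new_cp_profile(
    data.frame(theta_deg = s$theta_deg, r_deg = r_deg, value_um = s$value_um,
               valid = s$valid, weight = 1),
    location = sprintf("ring_%g", r_deg))
}

# list-valued ring sampler shared by sample_ring/sample_annulus and the
# extraction hot path
ring_core <- function(scan, r_deg, cal, n_theta, theta_offset_deg) {
  stop_if_not_scalar_num(r_deg, "r_deg", lower = 1e-12)
  if (n_theta < 4) stop("'n_theta' must be at least 4")
  theta <- seq.int(0L, n_theta - 1L) * (360 / n_theta)
  r_mm <- deg_to_mm(r_deg, cal)
  pos <- tsnit_to_xy(theta + theta_offset_deg, r_mm, scan$onh_center_mm,
                     scan$laterality)
  s <- bilinear_sample(scan, pos$x, pos$y)
  list(theta_deg = theta, value_um = s$value, valid = s$valid,
       weight = rep(1, n_theta))
}

annulus_core <- function(scan, r_inner_deg, r_outer_deg, cal, n_theta, n_r,
                         theta_offset_deg) {
  stop_if_not_scalar_num(r_inner_deg, "r_inner_deg", lower = 1e-12)
  if (r_outer_deg <= r_inner_deg)
    stop("'r_outer_deg' must exceed 'r_inner_deg'")
  h <- (r_outer_deg - r_inner_deg) / n_r
  radii <- r_inner_deg + (seq_len(n_r) - 0.5) * h
  parts <- lapply(radii, function(r)
    ring_core(scan, r, cal, n_theta, theta_offset_deg))
  list(theta_deg = unlist(lapply(parts, `[[`, "theta_deg")),
       r_deg = rep(radii, each = n_theta),
       value_um = unlist(lapply(parts, `[[`, "value_um")),
       valid = unlist(lapply(parts, `[[`, "valid")),
       weight = rep(radii, each = n_theta))
}

#' Sample a circumpapillary annulus
#'
#' Samples an `n_r x n_theta` polar grid between two visual-angle radii.
#' Radii are the midpoints of `n_r` equal-width shells and each sample
#' carries a weight proportional to its radius (the polar area element),
#' so weighted means are area-weighted annulus averages.
#'
#' @param scan a [raster_scan()].
#' @param r_inner_deg,r_outer_deg annulus radii in degrees,
#'   `0 < r_inner < r_outer`.
#' @param n_r number of radial shells.
#' @inheritParams sample_ring
#' @return A `cp_profile` data frame (see [sample_ring()]).
#' @export
sample_annulus <- function(scan, r_inner_deg, r_outer_deg,
                           cal = angle_calibration(), n_theta = 360,
                           n_r = 8, theta_offset_deg = 0) {
  s <- annulus_core(scan, r_inner_deg, r_outer_deg, cal, n_theta, n_r,
                    theta_offset_deg)
  new_cp_profile(
    data.frame(theta_deg = s$theta_deg, r_deg = s$r_deg,
               value_um = s$value_um, valid = s$valid, weight = s$weight),
    location = sprintf("annulus_%g_%g", r_inner_deg, r_outer_deg))
}

#' Quadrant sector schemes
#'
#' Angular partitions of the circumpapillary circle into
#' temporal/superior/nasal/inferior sectors in the TSNIT frame
#' (0 deg temporal, 90 superior for the right-eye anatomy).
#'
#' `"equal90"`: four 90-degree sectors centred on 0/90/180/270.
#' `"gdx"`: GDx Nerve Fiber Analyzer proportions — temporal 50, superior
#' 120, nasal 70, inferior 120 degrees.
#'
#' @param name `"equal90"` or `"gdx"`, or `"custom"` with `boundaries`.
#' @param boundaries optional named list for `"custom"`: for each of
#'   temporal/superior/nasal/inferior a `c(start, end)` in degrees
#'   (sectors may wrap through 0 and must partition the circle).
#' @return A `quadrant_scheme` data frame with columns `quadrant`,
#'   `start_deg`, `end_deg`.
#' @export
quadrant_scheme <- function(name = c("equal90", "gdx", "custom"),
                            boundaries = NULL) {
  name <- match.arg(name)
  b <- switch(name,
    equal90 = list(temporal = c(315, 45),  superior = c(45, 135),
                   nasal    = c(135, 225), inferior = c(225, 315)),
    gdx     = list(temporal = c(335, 25),  superior = c(25, 145),
                   nasal    = c(145, 215), inferior = c(215, 335)),
    custom  = boundaries)
  if (is.null(b) || !setequal(names(b),
                              c("temporal", "superior", "nasal", "inferior")))
    stop("custom scheme needs boundaries for all four quadrants")
  width <- vapply(b, function(se) (se[2] - se[1]) %% 360, 0)
  if (abs(sum(width) - 360) > 1e-9)
    stop("sector widths must sum to 360 degrees")
  df <- data.frame(quadrant = names(b),
                   start_deg = vapply(b, `[`, 0, 1) %% 360,
                   end_deg = vapply(b, `[`, 0, 2) %% 360,
                   row.names = NULL)
  attr(df, "scheme_name") <- name
  class(df) <- c("quadrant_scheme", class(df))
  df
}

# Vectorised quadrant lookup for anatomical TSNIT angles.
quadrant_of <- function(theta_deg, scheme) {
  th <- theta_deg %% 360
  out <- rep(NA_character_, length(th))
  for (k in seq_len(nrow(scheme))) {
    s <- scheme$start_deg[k]; e <- scheme$end_deg[k]
    hit <- if (s < e) th >= s & th < e else th >= s | th < e
    out[hit] <- scheme$quadrant[k]
  }
  out
}

#' Assign quadrant labels to a circumpapillary profile
#'
#' Labels every sample nasal/temporal/superior/inferior by its anatomical
#' TSNIT angle. Profiles produced by [sample_ring()]/[sample_annulus()]
#' already store anatomical angles (OS mirroring happens at sampling), so
#' the assignment is laterality-independent.
#'
#' @param profile a `cp_profile`.
#' @param scheme a [quadrant_scheme()].
#' @param laterality kept for interface symmetry; unused because profile
#'   angles are already anatomical.
#' @return The profile with a `quadrant` column added.
#' @export
assign_quadrants <- function(profile, scheme = quadrant_scheme("equal90"),
                             laterality = NULL) {
  profile$quadrant <- quadrant_of(profile$theta_deg, scheme)
  profile
}
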