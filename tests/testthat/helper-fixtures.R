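# Shared fixture builders. Everything is generated in code; no binary data.

# Noise-free phantom parameters (deterministic field, nothing masked)
noiseless_params <- function(...) {
  args <- list(sigma_subject_um = 0, sigma_scan_um = 0,
               sigma_assessor_um = 0, sigma_pixel_um = 0,
               missing_quadrant_prob = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_params, args)
}

# A raster scan holding an arbitrary function of physical position (mm),
# on the default 12 x 8 mm frame unless overridden.
scan_from_function <- function(f, nx = 600, ny = 80, ex = 12, ey = 8,
                               center = c(ex / 2, ey / 2),
                               laterality = "OD") {
  xs <- (seq_len(nx) - 0.5) * (ex / nx)
  ys <- (seq_len(ny) - 0.5) * (ey / ny)
  m <- outer(ys, xs, function(y, x) f(x, y))
  raster_scan(m, extent_x_mm = ex, extent_y_mm = ey, onh_center_mm = center,
              laterality = laterality)
}

constant_scan <- function(value = 100, ...) {
  scan_from_function(function(x, y) rep(value, length(x)), ...)
}

# Explicit double-loop two-way ANOVA oracle for the ICC (independent of
# the vectorised implementation path).
icc_oracle_loops <- function(x, y) {
  m <- unname(cbind(x, y))
  n <- nrow(m); k <- 2
  grand <- mean(m)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Per-quadrant summary table for a handful of scans at one location
summaries_at <- function(scans, location = "ring_6", n_theta = 60) {
  do.call(rbind, lapply(scans, summarize_scan, locations = location,
                        n_theta = n_theta))
}

feas_fixture_path <- function() {
  system.file("extdata", "feasibility_counts.json", package = "cprnfl")
}
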