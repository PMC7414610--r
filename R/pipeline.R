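# Pipeline configuration and the simulate -> extract -> reliability /
# feasibility workflow commands. These functions are the programmatic
# surface; inst/cli/cprnfl.R wraps them for shell use.

CONFIG_FIELDS <- c("um_per_degree", "scheme", "locations", "n_theta", "n_r",
                   "capture_threshold", "icc_form", "cov_method", "seed",
                   "crop_window_mm", "theta_offset_deg", "out_dir",
                   "log_level")

#' Build a validated run configuration
#'
#' Defaults follow the recommended hand-held OCT protocol: 288
#' um/degree calibration, 8 x 8 mm analysis window, rings at 4/5/6
#' degrees plus the two annuli, 1-degree angular sampling, equal90
#' quadrants, ICC(A,1) and the RMS within-subject CoV.
#'
#' @param um_per_degree visual-angle calibration.
#' @param scheme quadrant scheme name (`"equal90"` or `"gdx"`).
#' @param locations location codes, see [default_locations()].
#' @param n_theta,n_r polar sampling resolution.
#' @param capture_threshold quadrant capture threshold in \[0, 1\].
#' @param icc_form `"A1"` or `"C1"`.
#' @param cov_method `"rms"` or `"pairwise"`.
#' @param seed master RNG seed.
#' @param crop_window_mm analysis window `(w, h)` in mm; `NULL` disables
#'   cropping.
#' @param theta_offset_deg frame-rotation correction for sampling.
#' @param out_dir default output directory for the `run_*` commands.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(um_per_degree = 288, scheme = "equal90",
                       locations = default_locations(), n_theta = 360,
                       n_r = 8, capture_threshold = 0.9, icc_form = "A1",
                       cov_method = "rms", seed = 42,
                       crop_window_mm = c(8, 8), theta_offset_deg = 0,
                       out_dir = NULL, log_level = "info") {
  cfg <- list(um_per_degree = um_per_degree, scheme = scheme,
              locations = locations, n_theta = n_theta, n_r = n_r,
              capture_threshold = capture_threshold, icc_form = icc_form,
              cov_method = cov_method, seed = seed,
              crop_window_mm = crop_window_mm,
              theta_offset_deg = theta_offset_deg, out_dir = out_dir,
              log_level = log_level)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), CONFIG_FIELDS)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  stop_if_not_scalar_num(cfg$um_per_degree, "um_per_degree", lower = 1e-9)
  if (!cfg$scheme %in% c("equal90", "gdx"))
    stop("'scheme' must be 'equal90' or 'gdx'")
  lapply(cfg$locations, parse_location)
  stop_if_not_scalar_num(cfg$capture_threshold, "capture_threshold", 0, 1)
  if (!cfg$icc_form %in% c("A1", "C1")) stop("'icc_form' must be A1 or C1")
  if (!cfg$cov_method %in% c("rms", "pairwise"))
    stop("'cov_method' must be 'rms' or 'pairwise'")
  if (!is.null(cfg$crop_window_mm) && length(cfg$crop_window_mm) != 2)
    stop("'crop_window_mm' must be NULL or (w, h)")
  class(cfg) <- "run_config"
  cfg
}

#' Serialise / restore a run configuration
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `config_to_json` invisibly returns `path`; `config_from_json`
#'   returns the validated `run_config` (unknown keys are rejected).
#' @export
config_to_json <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$crop_window_mm)) cfg$crop_window_mm <-
      as.numeric(cfg$crop_window_mm)
  validate_config(cfg)
}

#' Short content hash of a configuration
#'
#' Embedded in every output file so results can be traced to the exact
#' analysis configuration that produced them. Runtime-only fields
#' (`out_dir`, `log_level`) are excluded: two runs of the same analysis
#' in different directories hash identically.
#'
#' @param cfg a [run_config()].
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  core <- unclass(cfg)
  core$out_dir <- NULL
  core$log_level <- NULL
  h <- fnv1a32(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA,
                                null = "null"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

cfg_cal <- function(cfg) angle_calibration(cfg$um_per_degree)
cfg_scheme <- function(cfg) quadrant_scheme(cfg$scheme)

log_info <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info"))
    message(sprintf(paste0("[cprnfl] ", fmt), ...))
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes every scan (CSV + JSON sidecar)
#' plus a `manifest.csv` listing the files, keyed by the config hash.
#'
#' @param cfg a [run_config()].
#' @param n_subjects,design,params see [simulate_cohort()].
#' @param glaucoma_factor global multiplicative thinning applied via the
#'   phantom parameters.
#' @param out_dir output directory (default `cfg$out_dir`).
#' @return Invisibly, the manifest data frame.
#' @export
run_simulate <- function(cfg = run_config(), n_subjects,
                         design = "test_retest", glaucoma_factor = 1,
                         params = phantom_params(), out_dir = cfg$out_dir) {
  if (is.null(out_dir)) stop("an output directory is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params$glaucoma_factor <- glaucoma_factor
  scans <- simulate_cohort(params, n_subjects, design, seed = cfg$seed)
  rows <- lapply(scans, function(s) {
    path <- write_scan(s, out_dir)
    data.frame(subject_id = s$subject_id, scan_id = s$scan_id,
               assessor_id = s$assessor_id, quality = s$quality,
               laterality = s$laterality, file = basename(path))
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), scan_id = character(),
               assessor_id = character(), quality = numeric(),
               laterality = character(), file = character())
  write_result_csv(manifest, file.path(out_dir, "manifest.csv"), cfg)
  log_info(cfg, "simulated %d scans (%s) into %s", length(scans), design,
           out_dir)
  invisible(manifest)
}

#' Extract per-quadrant measurements from scans
#'
#' For every scan: crop to the analysis window centred on the ONH, sample
#' all configured rings/annuli, summarise per quadrant. Accepts a
#' directory of scans written by [run_simulate()] or a list of
#' [raster_scan()] objects.
#'
#' @param cfg a [run_config()].
#' @param scans directory path or list of scans.
#' @param out_csv optional path for the tidy measurement CSV.
#' @param strict error (rather than warn and skip) on unreadable scans.
#' @return The tidy measurement data frame.
#' @export
run_extract <- function(cfg = run_config(), scans, out_csv = NULL,
                        strict = FALSE) {
  if (is.character(scans)) {
    files <- list.files(scans, pattern = "\\.csv$", full.names = TRUE)
    files <- files[basename(files) != "manifest.csv"]
    scans <- list()
    for (f in sort(files)) {
      s <- tryCatch(read_scan(f), error = function(e) e)
      if (inherits(s, "error")) {
        if (strict) stop(s)
        warning(sprintf("skipping '%s': %s", f, conditionMessage(s)))
        next
      }
      scans[[length(scans) + 1L]] <- s
    }
  }
  out <- lapply(scans, function(s) {
    if (!is.null(cfg$crop_window_mm))
      s <- crop_to_window(s, cfg$crop_window_mm)
    sm <- summarize_scan(s, cfg$locations, cfg_scheme(cfg), cfg_cal(cfg),
                         cfg$capture_threshold, cfg$n_theta, cfg$n_r,
                         cfg$theta_offset_deg)
    log_info(cfg, "%s/%s/%s: %d/%d cells captured", s$subject_id, s$scan_id,
             s$assessor_id, sum(sm$captured), nrow(sm))
    sm
  })
  res <- do.call(rbind, out)
  if (!is.null(out_csv)) write_result_csv(res, out_csv, cfg)
  res
}

#' Reliability analysis of an extracted measurement table
#'
#' Assigns arms per the design, builds matched pairs per location and
#' computes the full reliability table plus the ICC-vs-location sweep.
#'
#' @param cfg a [run_config()].
#' @param measurements tidy measurement table from [run_extract()].
#' @param design `"test_retest"` or `"interassessor"`.
#' @param out_prefix optional path prefix: writes
#'   `<prefix>_table.csv` and `<prefix>_sweep.csv`.
#' @return `list(table, sweep, pairs)`.
#' @export
run_reliability <- function(cfg = run_config(), measurements,
                            design = "test_retest", out_prefix = NULL) {
  pairs <- build_pairs(assign_arms(measurements, design))
  tab <- reliability_table(pairs, cfg$icc_form, cfg$cov_method)
  sweep <- icc_sweep(tab)
  if (!is.null(out_prefix)) {
    write_result_csv(tab, paste0(out_prefix, "_table.csv"), cfg)
    write_result_csv(sweep, paste0(out_prefix, "_sweep.csv"), cfg)
  }
  list(table = tab, sweep = sweep, pairs = pairs)
}

#' Feasibility analysis from a counts document
#'
#' Reads group-level attempt/exclusion counts and per-quadrant success
#' data (counts, or printed percentages to be reconstructed), validates
#' additivity, and emits the success-rate table on both denominators
#' with pooled totals.
#'
#' @param counts path to a JSON document with a `groups` array, or an
#'   equivalent list. Each group needs `group`, `eyes_attempted`,
#'   `eyes_possible`, `factor_counts`, and `success_counts` or
#'   `success_percent_possible`.
#' @param out_csv optional output CSV path.
#' @param cfg a [run_config()] (only used for output provenance).
#' @return The [feasibility_table()] data frame.
#' @export
run_feasibility <- function(counts, out_csv = NULL, cfg = run_config()) {
  if (is.character(counts))
    counts <- jsonlite::read_json(counts, simplifyVector = FALSE)
  groups <- lapply(counts$groups, function(g) {
    feasibility_counts(
      group = g$group, eyes_attempted = g$eyes_attempted,
      eyes_possible = g$eyes_possible,
      factor_counts = g$factor_counts %||% numeric(),
      success_counts = g$success_counts,
      success_percent_possible = g$success_percent_possible)
  })
  tab <- feasibility_table(groups)
  if (!is.null(out_csv)) write_result_csv(tab, out_csv, cfg)
  tab
}

#' Monte-Carlo ICC recovery for the phantom test-retest design
#'
#' Simulates many independent test-retest cohorts at a chosen pair of
#' variance components, runs the full pipeline (render, ring sampling,
#' quadrant summaries, pair building, ICC) on each, and reports how well
#' the estimated ICC recovers the population value
#' `sigma_subject^2 / (sigma_subject^2 + sigma_scan^2)` together with
#' the coverage of its confidence interval. Used for estimator
#' calibration; a coarse raster and angular grid keep it fast without
#' affecting quadrant means (the truth field is smooth).
#'
#' @param sigma_subject_um,sigma_scan_um variance components (um).
#' @param n_subjects subjects per cohort.
#' @param n_cohorts number of simulated cohorts.
#' @param seed master seed; cohort c uses stream `derive_seed(seed, c)`.
#' @param quadrant which quadrant's pairs to analyse.
#' @param r_deg measurement ring radius.
#' @param params base [phantom_params()]; the variance components, a
#'   coarse grid and zero pixel noise are imposed on top.
#' @param n_theta angular samples for the measurement ring.
#' @param icc_form passed to [icc_pairs()].
#' @return List with `true_icc`, `mean_icc`, `ci_coverage`, and the
#'   per-cohort `iccs`.
#' @export
estimate_icc_recovery <- function(sigma_subject_um = 12, sigma_scan_um = 4,
                                  n_subjects = 51, n_cohorts = 500,
                                  seed = 1, quadrant = "nasal", r_deg = 6,
                                  params = phantom_params(
                                    grid_n_ascans = 36, grid_n_bscans = 24),
                                  n_theta = 60, icc_form = "A1") {
  params$sigma_subject_um <- sigma_subject_um
  params$sigma_scan_um <- sigma_scan_um
  params$sigma_assessor_um <- 0
  params$sigma_pixel_um <- 0
  params$missing_quadrant_prob <- 0
  true_icc <- sigma_subject_um^2 / (sigma_subject_um^2 + sigma_scan_um^2)
  scheme <- quadrant_scheme("equal90")
  loc <- sprintf("ring_%g", r_deg)
  iccs <- numeric(n_cohorts)
  covered <- logical(n_cohorts)
  for (cc in seq_len(n_cohorts)) {
    scans <- simulate_cohort(params, n_subjects, "test_retest",
                             seed = derive_seed(seed, "cohort", cc))
    sm <- do.call(rbind, lapply(scans, summarize_scan, locations = loc,
                                scheme = scheme, n_theta = n_theta))
    pairs <- build_pairs(assign_arms(sm, "test_retest"))
    sel <- pairs$quadrant == quadrant
    ic <- icc_pairs(pairs$value_a_um[sel], pairs$value_b_um[sel], icc_form)
    iccs[cc] <- ic$icc
    covered[cc] <- ic$ci_low <= true_icc && true_icc <= ic$ci_high
  }
  list(true_icc = true_icc, mean_icc = mean(iccs),
       ci_coverage = mean(covered), iccs = iccs)
}
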