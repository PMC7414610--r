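# On-disk round-tripping: thickness maps as CSV matrices with JSON
# sidecars, profiles and tables as headed CSV.

#' Write a raster scan to disk
#'
#' Writes the thickness map as a plain CSV matrix (invalid pixels as
#' `NA`) plus a JSON sidecar `<stem>.json` carrying the geometric and
#' administrative metadata.
#'
#' @param scan a [raster_scan()].
#' @param dir output directory (created if missing).
#' @param stem file stem; default `<subject>_<scan>_<assessor>`.
#' @return Invisibly, the CSV path.
#' @export
write_scan <- function(scan, dir, stem = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% paste(scan$subject_id, scan$scan_id, scan$assessor_id,
                          sep = "_")
  csv <- file.path(dir, paste0(stem, ".csv"))
  m <- scan$thickness
  m[!scan$valid_mask] <- NA
  utils::write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(n_ascans = scan$n_ascans, n_bscans = scan$n_bscans,
               extent_mm = c(scan$extent_x_mm, scan$extent_y_mm),
               onh_center_mm = scan$onh_center_mm,
               laterality = scan$laterality, quality = scan$quality,
               subject_id = scan$subject_id, scan_id = scan$scan_id,
               assessor_id = scan$assessor_id)
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a raster scan written by [write_scan()]
#'
#' @param csv_path path to the CSV matrix; the sidecar is expected at the
#'   same stem with extension `.json`.
#' @return A [raster_scan()].
#' @export
read_scan <- function(csv_path) {
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(json_path))
    stop(sprintf("missing JSON sidecar for '%s'", csv_path))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(csv_path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  mask <- !is.na(m)
  m[!mask] <- 0
  raster_scan(thickness = m, valid_mask = mask,
              extent_x_mm = meta$extent_mm[1], extent_y_mm = meta$extent_mm[2],
              onh_center_mm = meta$onh_center_mm,
              laterality = meta$laterality, quality = meta$quality,
              subject_id = meta$subject_id, scan_id = meta$scan_id,
              assessor_id = meta$assessor_id)
}

# Write a table as CSV with a provenance comment line; read it back with
# read_result_csv() for an exact round trip.
write_result_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cprnfl %s config %s",
                     as.character(utils::packageVersion("cprnfl")),
                     if (is.null(config)) "none" else config_hash(config)),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
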