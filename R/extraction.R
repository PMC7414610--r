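# From scans to the measurement table: per-quadrant cpRNFL thickness at
# each ring/annulus location, plus the scan- and pair-level inclusion
# rules used before any reliability statistic is computed.

#' Default measurement locations
#'
#' Three rings at 4, 5 and 6 degrees plus the two annuli between them.
#'
#' @return Character vector of location codes (`"ring_<r>"`,
#'   `"annulus_<r1>_<r2>"`).
#' @export
default_locations <- function() {
  c("ring_4", "ring_5", "ring_6", "annulus_4_5", "annulus_5_6")
}

parse_location <- function(loc) {
  parts <- strsplit(loc, "_", fixed = TRUE)[[1]]
  if (parts[1] == "ring" && length(parts) == 2) {
    list(type = "ring", r = as.numeric(parts[2]))
  } else if (parts[1] == "annulus" && length(parts) == 3) {
    list(type = "annulus", r_inner = as.numeric(parts[2]),
         r_outer = as.numeric(parts[3]))
  } else stop(sprintf("unrecognised location code '%s'", loc))
}

sample_location <- function(scan, loc, cal, n_theta, n_r, theta_offset_deg) {
  l <- parse_location(loc)
  if (l$type == "ring")
    ring_core(scan, l$r, cal, n_theta, theta_offset_deg)
  else
    annulus_core(scan, l$r_inner, l$r_outer, cal, n_theta, n_r,
                 theta_offset_deg)
}

#' Summarise a scan into per-quadrant thickness means
#'
#' Samples every requested ring/annulus, assigns quadrant labels and
#' reduces to one row per (location x quadrant): the (area-)weighted mean
#' over valid samples, sample counts, and a `captured` flag. A quadrant
#' counts as captured when at least one sample is valid and the valid
#' fraction reaches `capture_threshold`; `mean_um` is `NA` otherwise.
#'
#' @param scan a [raster_scan()].
#' @param locations character vector of location codes
#'   (see [default_locations()]).
#' @param scheme a [quadrant_scheme()].
#' @param cal an [angle_calibration()].
#' @param capture_threshold minimum valid-sample fraction in \[0, 1\].
#' @param n_theta,n_r polar sampling resolution.
#' @param theta_offset_deg frame-rotation correction (see [sample_ring()]).
#' @return Data frame with columns `subject_id`, `scan_id`, `assessor_id`,
#'   `location`, `quadrant`, `mean_um`, `n_valid`, `n_total`, `captured`.
#' @export
summarize_scan <- function(scan, locations = default_locations(),
                           scheme = quadrant_scheme("equal90"),
                           cal = angle_calibration(),
                           capture_threshold = 0.9,
                           n_theta = 360, n_r = 8, theta_offset_deg = 0) {
  stop_if_not_scalar_num(capture_threshold, "capture_threshold",
                         lower = 0, upper = 1)
  quadrants <- scheme$quadrant
  nq <- length(quadrants)
  nl <- length(locations)
  mean_v <- rep(NA_real_, nl * nq)
  nval_v <- integer(nl * nq); ntot_v <- integer(nl * nq)
  cap_v <- logical(nl * nq)
  for (li in seq_len(nl)) {
    prof <- sample_location(scan, locations[li], cal, n_theta, n_r,
                            theta_offset_deg)
    q <- quadrant_of(prof$theta_deg, scheme)
    for (qi in seq_len(nq)) {
      idx <- (li - 1L) * nq + qi
      sel <- q == quadrants[qi]
      ntot_v[idx] <- sum(sel)
      ok <- sel & prof$valid
      nval_v[idx] <- sum(ok)
      cap_v[idx] <- nval_v[idx] > 0 &&
        nval_v[idx] / ntot_v[idx] >= capture_threshold
      if (cap_v[idx]) {
        w <- prof$weight[ok]
        mean_v[idx] <- sum(prof$value_um[ok] * w) / sum(w)
      }
    }
  }
  data.frame(subject_id = scan$subject_id, scan_id = scan$scan_id,
             assessor_id = scan$assessor_id,
             location = rep(locations, each = nq),
             quadrant = rep(quadrants, nl), mean_um = mean_v,
             n_valid = nval_v, n_total = ntot_v, captured = cap_v)
}

#' Pair-inclusion rule for two measurement arms
#'
#' A subject enters the reliability analysis at a location when at least
#' three quadrants were captured in both arms — the same quadrants.
#'
#' @param summaries_a,summaries_b per-quadrant summary rows
#'   (as from [summarize_scan()]) for one subject, one location, one arm
#'   each.
#' @param min_common minimum number of co-captured quadrants (default 3).
#' @return `list(included = logical, common_quadrants = character)`.
#' @export
include_pair <- function(summaries_a, summaries_b, min_common = 3) {
  qa <- summaries_a$quadrant[summaries_a$captured]
  qb <- summaries_b$quadrant[summaries_b$captured]
  common <- intersect(qa, qb)
  list(included = length(common) >= min_common, common_quadrants = common)
}

#' Build matched measurement pairs from a two-arm cohort
#'
#' Applies [include_pair()] per subject and location, then emits one pair
#' per co-captured quadrant, plus an `"Average"` pair — the unweighted
#' mean of the four quadrant means — only for subjects with all four
#' quadrants captured in both arms (the rule used for the `Average` rows
#' of a reliability table).
#'
#' @param summaries per-quadrant summaries for the whole cohort with an
#'   `arm` column holding exactly two values.
#' @param arm_levels optional length-2 character vector fixing which arm
#'   is `a` (first) and `b` (second); defaults to sorted unique values.
#' @param min_common passed to [include_pair()].
#' @return Data frame with columns `subject_id`, `location`, `quadrant`
#'   (four quadrants and `"Average"`), `value_a_um`, `value_b_um`,
#'   `arm_a`, `arm_b`.
#' @export
build_pairs <- function(summaries, arm_levels = NULL, min_common = 3) {
  if (!"arm" %in% names(summaries))
    stop("'summaries' needs an 'arm' column; see assign_arms()")
  if (is.null(arm_levels)) arm_levels <- sort(unique(summaries$arm))
  if (length(arm_levels) != 2)
    stop("exactly two arms are required")
  sa <- summaries[summaries$arm == arm_levels[1], ]
  sb <- summaries[summaries$arm == arm_levels[2], ]
  subj_a <- unique(sa$subject_id); subj_b <- unique(sb$subject_id)
  if (!setequal(subj_a, subj_b))
    stop(sprintf("subject sets differ between arms: %s",
                 paste(union(setdiff(subj_a, subj_b), setdiff(subj_b, subj_a)),
                       collapse = ", ")))
  o_subj <- character(); o_loc <- character(); o_quad <- character()
  o_a <- numeric(); o_b <- numeric()
  for (loc in unique(summaries$location)) {
    la <- sa[sa$location == loc, ]
    lb <- sb[sb$location == loc, ]
    subjects <- sort(unique(la$subject_id))
    quads <- sort(unique(la$quadrant))
    # subjects x quadrants matrices of captured means, NA when uncaptured
    cell <- function(d) {
      m <- matrix(NA_real_, length(subjects), length(quads))
      keep <- d$captured
      m[cbind(match(d$subject_id[keep], subjects),
              match(d$quadrant[keep], quads))] <- d$mean_um[keep]
      m
    }
    A <- cell(la); B <- cell(lb)
    common <- !is.na(A) & !is.na(B)
    n_common <- rowSums(common)
    for (si in which(n_common >= min_common)) {
      qs <- quads[common[si, ]]
      va <- A[si, common[si, ]]; vb <- B[si, common[si, ]]
      o_subj <- c(o_subj, rep(subjects[si], length(qs)))
      o_loc <- c(o_loc, rep(loc, length(qs)))
      o_quad <- c(o_quad, qs); o_a <- c(o_a, va); o_b <- c(o_b, vb)
      if (length(qs) == 4) {
        o_subj <- c(o_subj, subjects[si]); o_loc <- c(o_loc, loc)
        o_quad <- c(o_quad, "Average")
        o_a <- c(o_a, mean(va)); o_b <- c(o_b, mean(vb))
      }
    }
  }
  data.frame(subject_id = o_subj, location = o_loc, quadrant = o_quad,
             value_a_um = o_a, value_b_um = o_b,
             arm_a = if (length(o_subj)) arm_levels[1] else character(),
             arm_b = if (length(o_subj)) arm_levels[2] else character())
}

#' Attach arm labels for a paired design
#'
#' For `"test_retest"` the arm is the scan (`S1` = high quality first
#' scan vs `S2`); for `"interassessor"` it is the assessor (`A1` vs
#' `A2`).
#'
#' @param summaries cohort summaries from [summarize_scan()].
#' @param design `"test_retest"` or `"interassessor"`.
#' @return `summaries` with an `arm` column added.
#' @export
assign_arms <- function(summaries, design = c("test_retest", "interassessor")) {
  design <- match.arg(design)
  summaries$arm <- if (design == "test_retest") summaries$scan_id
                   else summaries$assessor_id
  summaries
}
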