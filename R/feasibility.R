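# Feasibility bookkeeping: acquisition-attempt accounting per group,
# per-quadrant and full-profile success rates on two denominators, and
# pooled totals via integer-count reconstruction of printed percentages.

FEAS_MEASURES <- c("nasal", "temporal", "inferior", "superior", "full")

#' Feasibility counts for one participant group
#'
#' Records how many eyes were attempted, how many could be imaged in 3D,
#' the per-factor exclusion counts, and the per-quadrant / full-profile
#' success counts among imageable eyes. Validates the additivity
#' constraint `eyes_possible + sum(factor_counts) == eyes_attempted`.
#'
#' @param group group label (e.g. `"glaucoma"`, `"controls"`).
#' @param eyes_attempted,eyes_possible eye counts.
#' @param factor_counts named integer vector/list of eyes excluded per
#'   factor (may be empty when every attempted eye was imageable).
#' @param success_counts named vector over
#'   `nasal/temporal/inferior/superior/full` of success counts among
#'   imageable eyes. Alternatively supply `success_percent_possible`.
#' @param success_percent_possible named vector of printed success
#'   percentages on the imageable-eyes basis; converted to integer
#'   counts with [reconstruct_counts()].
#' @return A `feasibility_counts` object.
#' @export
feasibility_counts <- function(group, eyes_attempted, eyes_possible,
                               factor_counts = numeric(),
                               success_counts = NULL,
                               success_percent_possible = NULL) {
  factor_counts <- unlist(factor_counts)
  if (eyes_possible + sum(factor_counts) != eyes_attempted)
    stop(sprintf(
      "inconsistent counts for '%s': possible (%d) + excluded (%d) != attempted (%d)",
      group, eyes_possible, sum(factor_counts), eyes_attempted))
  if (is.null(success_counts)) {
    if (is.null(success_percent_possible))
      stop("supply 'success_counts' or 'success_percent_possible'")
    pct <- unlist(success_percent_possible)
    success_counts <- vapply(pct, function(p)
      reconstruct_counts(p, eyes_possible)$count, 0)
  } else success_counts <- unlist(success_counts)
  miss <- setdiff(FEAS_MEASURES, names(success_counts))
  if (length(miss))
    stop(sprintf("missing success entries: %s", paste(miss, collapse = ", ")))
  if (any(success_counts > eyes_possible))
    stop("success counts cannot exceed the number of imageable eyes")
  structure(list(group = group, eyes_attempted = eyes_attempted,
                 eyes_possible = eyes_possible,
                 factor_counts = factor_counts,
                 success_counts = success_counts[FEAS_MEASURES]),
            class = "feasibility_counts")
}

#' Success rates on a chosen denominator
#'
#' Rate in percent per quadrant and for the full profile, on the
#' imageable-eyes (`"possible"`) or all-attempts (`"attempted"`) basis.
#' Full precision is returned; report output should be rounded to one
#' decimal with [round_half_away()]. A zero denominator yields `NaN`
#' with a warning rather than an error.
#'
#' @param counts a [feasibility_counts()].
#' @param basis `"possible"` or `"attempted"`.
#' @return Named numeric vector of percentages.
#' @export
success_rates <- function(counts, basis = c("possible", "attempted")) {
  basis <- match.arg(basis)
  den <- if (basis == "possible") counts$eyes_possible else counts$eyes_attempted
  if (den == 0) {
    warning(sprintf("zero denominator for basis '%s' in group '%s'",
                    basis, counts$group))
    return(stats::setNames(rep(NaN, length(FEAS_MEASURES)), FEAS_MEASURES))
  }
  100 * counts$success_counts / den
}

#' Reconstruct an integer count from a printed percentage
#'
#' Inverts a printed rate: `count = round(rate / 100 * denominator)`
#' (half away from zero), with the absolute residual returned as a
#' consistency diagnostic — a residual near 0.5 flags a percentage that
#' is not consistent with any integer count.
#'
#' @param rate_percent printed percentage.
#' @param denominator integer denominator.
#' @return `list(count, residual)`.
#' @export
reconstruct_counts <- function(rate_percent, denominator) {
  raw <- rate_percent / 100 * denominator
  count <- round_half_away(raw)
  list(count = count, residual = abs(count - raw))
}

#' Pool success rates across groups
#'
#' Sums integer success counts and denominators over groups before
#' forming the rate, so pooled rows are consistent with the per-group
#' integer counts (percent averaging would not be).
#'
#' @param groups list of [feasibility_counts()].
#' @param basis `"possible"` or `"attempted"`.
#' @return Named numeric vector of pooled percentages.
#' @export
pooled_rates <- function(groups, basis = c("possible", "attempted")) {
  basis <- match.arg(basis)
  den <- sum(vapply(groups, function(g)
    if (basis == "possible") g$eyes_possible else g$eyes_attempted, 0))
  if (den == 0) stop("zero pooled denominator")
  num <- Reduce(`+`, lapply(groups, function(g) g$success_counts))
  100 * num / den
}

#' Feasibility table over groups, bases and pooled totals
#'
#' The report-shaped success-rate table: one row per (group x basis)
#' plus pooled `Total` rows, with per-quadrant and full-profile
#' percentages rounded to one decimal (half away from zero).
#'
#' @param groups list of [feasibility_counts()].
#' @return Data frame with columns `group`, `basis`, `n`, and one column
#'   per measure.
#' @export
feasibility_table <- function(groups) {
  rows <- list()
  add_row <- function(group, basis, n, rates) {
    r <- as.list(round_half_away(rates, 1))
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(group = group, basis = basis, n = n), as.data.frame(r))
  }
  for (g in groups) {
    add_row(g$group, "possible", g$eyes_possible, success_rates(g, "possible"))
    add_row(g$group, "attempted", g$eyes_attempted,
            success_rates(g, "attempted"))
  }
  if (length(groups) > 1) {
    np <- sum(vapply(groups, function(g) g$eyes_possible, 0))
    na <- sum(vapply(groups, function(g) g$eyes_attempted, 0))
    add_row("Total", "possible", np, pooled_rates(groups, "possible"))
    add_row("Total", "attempted", na, pooled_rates(groups, "attempted"))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
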