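# Agreement statistics for paired measurements: ICC (two-way ANOVA
# forms with F-based confidence intervals), within-subject CoV, bias
# with CI/p from the balanced two-way fixed-effect model, Bland-Altman
# limits of agreement, and the table/sweep builders.

#' Intraclass correlation for paired measurements
#'
#' Computes the two-way, single-measure ICC from the two-way ANOVA mean
#' squares (rows = subjects, columns = raters/arms) by direct summation.
#' `form = "A1"` is McGraw-Wong ICC(A,1) — two-way random effects,
#' absolute agreement — which penalises systematic offsets between arms;
#' `form = "C1"` is the consistency form ICC(C,1). 95% confidence limits
#' use the F-distribution method (Satterthwaite degrees of freedom for
#' the absolute-agreement form).
#'
#' @param x,y paired measurements (same length, no NA).
#' @param form `"A1"` (absolute agreement, default) or `"C1"`
#'   (consistency).
#' @param conf confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `form`, `n`, mean
#'   squares `msr`/`msc`/`mse`, and `degenerate` (`TRUE` when the total
#'   variance is zero so the ICC is undefined — `icc` is then `NA`,
#'   never reported as 1).
#' @export
icc_pairs <- function(x, y, form = c("A1", "C1"), conf = 0.95) {
  form <- match.arg(form)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  mse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2) /
    ((n - 1) * (k - 1))
  if (msr + msc + mse <= .Machine$double.eps * max(1, grand^2)) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                form = form, n = n, msr = msr, msc = msc, mse = mse,
                degenerate = TRUE))
  }
  alpha <- 1 - conf
  if (form == "C1") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) {
      lo <- hi <- icc <- 1
    } else {
      fobs <- msr / mse
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse <= 0 && msc <= 0) {
      lo <- hi <- icc <- 1
    } else {
      r <- min(icc, 1 - 1e-12)
      a <- (k * r) / (n * (1 - r))
      b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    }
  }
  list(icc = icc, ci_low = max(-1, lo), ci_high = min(1, hi),
       form = form, n = n, msr = msr, msc = msc, mse = mse,
       degenerate = FALSE)
}

#' Within-subject coefficient of variation
#'
#' Default (`method = "rms"`) is the within-subject SD of Bland,
#' `S_w = sqrt(sum(d_i^2) / (2 n))` with `d_i` the paired differences —
#' the root-mean-square of the per-pair SDs — expressed as a percentage
#' of the grand mean. `method = "pairwise"` instead averages the per-pair
#' CoVs (per-pair SD over per-pair mean).
#'
#' @param x,y paired measurements.
#' @param method `"rms"` (default) or `"pairwise"`.
#' @return CoV in percent.
#' @export
cov_percent <- function(x, y, method = c("rms", "pairwise")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 1) stop("no complete pairs")
  if (method == "rms") {
    gm <- mean(c(x, y))
    if (gm <= 0) stop("grand mean must be positive for a CoV")
    sw <- sqrt(sum((x - y)^2) / (2 * n))
    100 * sw / gm
  } else {
    pm <- (x + y) / 2
    if (any(pm <= 0)) stop("pair means must be positive for a CoV")
    psd <- abs(x - y) / sqrt(2)
    mean(100 * psd / pm)
  }
}

#' Bias between two measurement arms
#'
#' Fits the balanced two-way additive fixed-effect model
#' `value = mu + arm + subject` by least squares and reports the arm
#' contrast `a - b` with its 95% CI and p-value. With two arms and
#' complete pairs this estimate, its CI and its p-value coincide exactly
#' with the paired t-test on the differences (t on n - 1 df).
#'
#' @param x,y paired measurements; sign convention `bias = mean(x - y)`.
#' @param conf confidence level.
#' @return List with `bias`, `ci_low`, `ci_high`, `p`, `n`, `df` and
#'   `degenerate` (`TRUE` when the paired differences have zero
#'   variance, so the CI has zero width and `p` is 0 or 1).
#' @export
bias_test <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("at least 2 complete pairs are required")
  d <- x - y
  if (stats::sd(d) == 0) {
    b <- mean(d)
    return(list(bias = b, ci_low = b, ci_high = b,
                p = if (b == 0) 1 else 0, n = n, df = n - 1,
                degenerate = TRUE))
  }
  dat <- data.frame(value = c(x, y),
                    arm = factor(rep(c("a", "b"), each = n), c("b", "a")),
                    subject = factor(rep(seq_len(n), 2)))
  fit <- stats::lm(value ~ arm + subject, data = dat)
  co <- summary(fit)$coefficients["arma", ]
  tq <- stats::qt(1 - (1 - conf) / 2, fit$df.residual)
  list(bias = unname(co["Estimate"]),
       ci_low = unname(co["Estimate"] - tq * co["Std. Error"]),
       ci_high = unname(co["Estimate"] + tq * co["Std. Error"]),
       p = unname(co["Pr(>|t|)"]), n = n, df = fit$df.residual,
       degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Per pair computes the mean `m = (x + y) / 2` and difference
#' `d = x - y`; reports the bias `mean(d)`, the 95% limits of agreement
#' `bias +/- 1.96 sd(d)`, and the OLS trend of `d` on `m` (slope and
#' p-value), plus the point list for plotting.
#'
#' @param x,y paired measurements.
#' @return List with `bias`, `loa_low`, `loa_high`, `trend_slope`,
#'   `trend_p` and a `points` data frame (`mean`, `diff`).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  m <- (x + y) / 2
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  slope <- NA_real_; p <- NA_real_
  if (length(d) >= 3 && stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    # a perfect fit (zero residuals) is legitimate here: degenerate
    # fixtures produce it, so silence summary.lm's warning
    sm <- suppressWarnings(summary(fit))$coefficients
    slope <- sm["m", "Estimate"]
    p <- sm["m", "Pr(>|t|)"]
    if (is.nan(p)) p <- NA_real_
  }
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       trend_slope = slope, trend_p = p,
       points = data.frame(mean = m, diff = d))
}

#' Reliability table over quadrants and locations
#'
#' One row per (measure x location), measures being the four quadrants
#' plus `"Average"`: pair count, per-arm mean and SD, bias with CI and
#' p, within-subject CoV%, ICC with CI and Bland-Altman limits/trend —
#' the row shape of a clinical repeatability/reproducibility table.
#' Cells with fewer than 3 pairs are emitted with `NA` statistics.
#'
#' @param pairs pair table from [build_pairs()].
#' @param icc_form,cov_method,conf passed to [icc_pairs()],
#'   [cov_percent()], [bias_test()].
#' @return Data frame of class `reliability_table`.
#' @export
reliability_table <- function(pairs, icc_form = "A1", cov_method = "rms",
                              conf = 0.95) {
  measures <- c("nasal", "temporal", "inferior", "superior", "Average")
  locs <- unique(pairs$location)
  out <- list()
  for (loc in locs) {
    for (q in measures) {
      sel <- pairs$location == loc & pairs$quadrant == q
      a <- pairs$value_a_um[sel]; b <- pairs$value_b_um[sel]
      n <- length(a)
      row <- data.frame(
        location = loc, quadrant = q, n_pairs = n,
        mean_a_um = NA_real_, sd_a_um = NA_real_,
        mean_b_um = NA_real_, sd_b_um = NA_real_,
        bias_um = NA_real_, bias_lci = NA_real_, bias_uci = NA_real_,
        bias_p = NA_real_, cov_percent = NA_real_,
        icc = NA_real_, icc_lci = NA_real_, icc_uci = NA_real_,
        ba_loa_low = NA_real_, ba_loa_high = NA_real_,
        ba_trend_slope = NA_real_, ba_trend_p = NA_real_)
      if (n >= 3) {
        bt <- bias_test(a, b, conf)
        ic <- icc_pairs(a, b, icc_form, conf)
        ba <- bland_altman(a, b)
        row$mean_a_um <- mean(a); row$sd_a_um <- stats::sd(a)
        row$mean_b_um <- mean(b); row$sd_b_um <- stats::sd(b)
        row$bias_um <- bt$bias; row$bias_lci <- bt$ci_low
        row$bias_uci <- bt$ci_high; row$bias_p <- bt$p
        row$cov_percent <- cov_percent(a, b, cov_method)
        row$icc <- ic$icc; row$icc_lci <- ic$ci_low; row$icc_uci <- ic$ci_high
        row$ba_loa_low <- ba$loa_low; row$ba_loa_high <- ba$loa_high
        row$ba_trend_slope <- ba$trend_slope; row$ba_trend_p <- ba$trend_p
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("reliability_table", class(res))
  res
}

#' ICC-versus-location sweep
#'
#' The "ICC at varying distances from the optic nerve centre" view of a
#' reliability table: location, measure, ICC and its confidence limits,
#' ordered by location radius.
#'
#' @param results a [reliability_table()].
#' @return Data frame with columns `location`, `quadrant`, `icc`,
#'   `icc_lci`, `icc_uci`, `n_pairs`.
#' @export
icc_sweep <- function(results) {
  loc_radius <- vapply(results$location, function(l) {
    p <- parse_location(l)
    if (p$type == "ring") p$r else (p$r_inner + p$r_outer) / 2
  }, 0)
  out <- results[order(loc_radius, results$quadrant),
                 c("location", "quadrant", "icc", "icc_lci", "icc_uci",
                   "n_pairs")]
  rownames(out) <- NULL
  out
}
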