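#' Pearson correlation with a qualitative band
#'
#' Bands (applied to |r|): >= 0.8 "very strong", 0.6-0.8 "moderately
#' strong", 0.3-0.5 "fair", < 0.3 "poor". The unassigned interval
#' [0.5, 0.6) is mapped to "fair" — a documented choice, boundaries are
#' left-closed upwards (0.8 is "very strong", 0.6 "moderately strong",
#' 0.3 "fair").
#'
#' @param x,y Numeric vectors, length >= 3, nonzero variance.
#' @return `list(r, band)`.
#' @export
pearson_with_band <- function(x, y) {
  check_paired(x, y, n_min = 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  list(r = r, band = correlation_band(r))
}

correlation_band <- function(r) {
  a <- abs(r)
  if (a >= 0.8) "very strong"
  else if (a >= 0.6) "moderately strong"
  else if (a >= 0.3) "fair"
  else "poor"
}

icc_band <- function(icc) {
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "fair"
  else "poor"
}

check_paired <- function(x, y, n_min = 3) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired sample", call. = FALSE)
  if (length(x) < n_min) {
    stop(sprintf("need at least %d pairs", n_min), call. = FALSE)
  }
  invisible(TRUE)
}

#' Ordinary least products (geometric-mean) regression
#'
#' Model-II regression for method comparison: slope = sign(r)·sd(y)/sd(x),
#' intercept through the bivariate mean. 95% CIs use the classical
#' B-statistic construction: B = t²(0.975, n-2)·(1-r²)/(n-2),
#' slope CI = slope·(sqrt(B+1) ± sqrt(B)), intercept CI obtained by passing
#' the slope CI endpoints through (mean x, mean y). Proportional bias is
#' declared when the slope CI excludes 1, fixed bias when the intercept CI
#' excludes 0.
#'
#' @param x Reference method values (peak OUES by convention).
#' @param y Comparison method values.
#' @return A list of class `olp_fit`: `slope`, `slope_ci`, `intercept`,
#'   `intercept_ci`, `r`, `r2`, `fixed_bias`, `proportional_bias`, `n`.
#' @export
olp_regression <- function(x, y) {
  check_paired(x, y, n_min = 3)
  n <- length(x)
  r <- stats::cor(x, y)
  if (is.na(r) || r == 0) stop("r = 0: OLP slope sign undefined", call. = FALSE)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  B <- stats::qt(0.975, n - 2)^2 * (1 - r^2) / (n - 2)
  slope_ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  intercept_ci <- sort(mean(y) - slope_ci * mean(x))
  structure(
    list(slope = slope, slope_ci = slope_ci,
         intercept = intercept, intercept_ci = intercept_ci,
         r = r, r2 = r^2,
         proportional_bias = slope_ci[1] > 1 || slope_ci[2] < 1,
         fixed_bias = intercept_ci[1] > 0 || intercept_ci[2] < 0,
         n = n),
    class = "olp_fit"
  )
}

#' Typical percentage error of paired measurements
#'
#' TE = sd(x - y)/sqrt(2), expressed as a percentage of the grand mean of
#' all pooled observations. Values under 10% are conventionally considered
#' acceptable in method comparison.
#'
#' @param x,y Paired numeric vectors.
#' @return `te_pct`, a single percentage.
#' @export
typical_error_pct <- function(x, y) {
  check_paired(x, y, n_min = 2)
  grand <- mean(c(x, y))
  if (grand <= 0) stop("pooled mean must be positive for a percentage error", call. = FALSE)
  te <- stats::sd(x - y) / sqrt(2)
  100 * te / grand
}

#' Intraclass correlation ICC(3,1) with 95% CI
#'
#' Two-way mixed-effects, consistency, single-measures ICC computed from the
#' mean squares of the subject-by-method decomposition:
#' ICC = (MSR - MSE)/(MSR + (k-1)·MSE). The 95% CI uses the F-distribution
#' bounds on F = MSR/MSE. Bands: >= 0.75 "excellent", 0.60-0.75 "good",
#' 0.40-0.60 "fair", < 0.40 "poor".
#'
#' @param x,y Paired numeric vectors (two methods, one row per subject).
#' @return `list(icc, ci, band, msr, mse)`.
#' @export
icc_consistency <- function(x, y) {
  check_paired(x, y, n_min = 5)
  m <- cbind(x, y)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0) stop("zero between-subject variance: ICC undefined", call. = FALSE)
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f_obs <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- f_obs / stats::qf(0.975, df1, df2)
  fu <- f_obs * stats::qf(0.975, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  list(icc = icc, ci = ci, band = icc_band(icc), msr = msr, mse = mse)
}

#' Bland-Altman analysis on percentage differences
#'
#' Per-subject difference d_i = 100·(x_i − y_i)/((x_i + y_i)/2); the limits
#' of agreement are mean(d) ± 1.96·sd(d), symmetric about the mean by
#' construction.
#'
#' @param x,y Paired numeric vectors with positive pair means.
#' @return `list(mean_pct, lo, hi, sd_pct, per_subject)`.
#' @export
bland_altman_pct <- function(x, y) {
  check_paired(x, y, n_min = 3)
  pair_mean <- (x + y) / 2
  if (any(pair_mean <= 0)) stop("non-positive pair mean: percentage difference undefined", call. = FALSE)
  d <- 100 * (x - y) / pair_mean
  m <- mean(d); s <- stats::sd(d)
  list(mean_pct = m, lo = m - 1.96 * s, hi = m + 1.96 * s,
       sd_pct = s, per_subject = d)
}

#' Two-sided paired t-test p-value
#'
#' Degenerate zero-variance differences are reported with a flag instead of
#' an error: identical vectors give p = 1, a constant nonzero shift gives
#' p = 0.
#'
#' @param x,y Paired numeric vectors.
#' @return `list(p, t, df, degenerate)`.
#' @export
paired_t <- function(x, y) {
  check_paired(x, y, n_min = 3)
  d <- x - y
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
    return(list(p = p, t = NA_real_, df = length(d) - 1L, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(p = ht$p.value, t = unname(ht$statistic),
       df = unname(ht$parameter), degenerate = FALSE)
}

#' One-way repeated-measures ANOVA with Bonferroni post hocs
#'
#' Subjects are rows, conditions columns (e.g. OUES up to AerT, up to AnT,
#' peak). The F test uses the subject-by-condition error term; partial eta
#' squared = SS_condition/(SS_condition + SS_error). Pairwise paired t-tests
#' are Bonferroni-adjusted by the number of pairs.
#'
#' @param m Complete numeric matrix or data frame, n subjects × k conditions.
#' @return A list of class `rm_anova`: `F`, `df`, `p`, `partial_eta2`,
#'   `pairwise` (tibble with pair labels, raw and adjusted p).
#' @export
rm_anova_bonferroni <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(k))
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) 0 else ms_cond / ms_err
  p <- if (ms_err == 0 && ss_cond == 0) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)
  eta2 <- if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err)
  pairs <- utils::combn(k, 2)
  pw <- apply(pairs, 2, function(ij) paired_t(m[, ij[1]], m[, ij[2]])$p)
  pairwise <- tibble::tibble(
    pair = apply(pairs, 2, function(ij)
      paste(colnames(m)[ij[1]], colnames(m)[ij[2]], sep = " vs ")),
    p_raw = pw,
    p_bonferroni = pmin(pw * ncol(pairs), 1)
  )
  structure(
    list(F = f, df = c(df1, df2), p = p, partial_eta2 = eta2, pairwise = pairwise),
    class = "rm_anova"
  )
}

#' Full agreement report between two OUES methods
#'
#' Assembles the method-comparison battery into one record: R², OLP slope
#' and intercept with 95% CIs, mean difference (comparison − reference) with
#' the observed range, paired-t p, typical percentage error, ICC(3,1) with
#' CI and band, and Bland-Altman percentage limits. Also reports the mean
#' difference as a percentage of the reference mean.
#'
#' @param peak Reference method values (peak OUES).
#' @param submax Comparison method values (a submaximal OUES).
#' @param label Report label.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(peak, submax, label = "peak vs submax") {
  check_paired(peak, submax, n_min = 5)
  olp <- olp_regression(peak, submax)
  diffs <- submax - peak
  # Bland-Altman on submaximal - peak so its mean carries the same sign as
  # mean_diff
  ba <- bland_altman_pct(submax, peak)
  icc <- icc_consistency(peak, submax)
  structure(
    list(label = label,
         n = length(peak),
         r = olp$r, r2 = olp$r2, r_band = correlation_band(olp$r),
         olp = olp,
         mean_diff = mean(diffs),
         diff_range = range(diffs),
         mean_diff_pct = 100 * mean(diffs) / mean(peak),
         p_paired_t = paired_t(peak, submax)$p,
         te_pct = typical_error_pct(peak, submax),
         te_acceptable = typical_error_pct(peak, submax) <= 10,
         icc = icc$icc, icc_ci = icc$ci, icc_band = icc$band,
         ba_mean_pct = ba$mean_pct, ba_lo_pct = ba$lo, ba_hi_pct = ba$hi),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  R2 %.2f | OLP slope %.2f [%.2f, %.2f] | intercept %.1f [%.1f, %.1f]\n",
              x$r2, x$olp$slope, x$olp$slope_ci[1], x$olp$slope_ci[2],
              x$olp$intercept, x$olp$intercept_ci[1], x$olp$intercept_ci[2]))
  cat(sprintf("  mean diff %.1f (%.1f to %.1f; %.1f%% of reference) | p = %.2f\n",
              x$mean_diff, x$diff_range[1], x$diff_range[2], x$mean_diff_pct,
              x$p_paired_t))
  cat(sprintf("  TE %.1f%%%s | ICC %.2f [%.2f, %.2f] (%s) | BA %.2f%% [%.2f, %.2f]\n",
              x$te_pct, if (x$te_acceptable) " (acceptable)" else "",
              x$icc, x$icc_ci[1], x$icc_ci[2], x$icc_band,
              x$ba_mean_pct, x$ba_lo_pct, x$ba_hi_pct))
  invisible(x)
}

#' Flatten an agreement report to a one-row tibble
#'
#' Convenience for building method-comparison tables (one row per
#' reference/comparison pairing and scaling).
#'
#' @param report An `agreement_report`.
#' @return A one-row tibble.
#' @export
agreement_row <- function(report) {
  tibble::tibble(
    comparison = report$label, n = report$n, r = report$r, r2 = report$r2,
    slope = report$olp$slope, slope_lo = report$olp$slope_ci[1],
    slope_hi = report$olp$slope_ci[2],
    intercept = report$olp$intercept, intercept_lo = report$olp$intercept_ci[1],
    intercept_hi = report$olp$intercept_ci[2],
    mean_diff = report$mean_diff, diff_min = report$diff_range[1],
    diff_max = report$diff_range[2], mean_diff_pct = report$mean_diff_pct,
    p = report$p_paired_t, te_pct = report$te_pct,
    icc = report$icc, icc_lo = report$icc_ci[1], icc_hi = report$icc_ci[2],
    icc_band = report$icc_band,
    ba_mean_pct = report$ba_mean_pct, ba_lo_pct = report$ba_lo_pct,
    ba_hi_pct = report$ba_hi_pct
  )
}
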