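#' Two-segment piecewise-linear breakpoint fit
#'
#' Shared engine for the V-slope (VCO2 vs VO2) and VE-vs-VCO2 secondary
#' threshold criteria. Every observed x-value that leaves at least
#' `min_seg` points on each side is tried as a candidate breakpoint; two
#' independent least-squares lines are fitted and the candidate minimising
#' the pooled residual sum of squares wins. Ties go to the earlier
#' breakpoint. No continuity constraint is imposed at the knee.
#'
#' @param x,y Paired numeric vectors, `x` sorted ascending, length >= 8.
#' @param min_seg Minimum points per segment (default 3).
#' @return A list of class `breakpoint_fit`: `bp_x`, `slope_lo`, `slope_hi`,
#'   `intercept_lo`, `intercept_hi`, `rss`, `n_lo`, `n_hi`.
#' @export
piecewise_breakpoint <- function(x, y, min_seg = 3L) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 2L * min_seg + 2L || n < 8L) {
    stop("need at least 8 points for a breakpoint fit", call. = FALSE)
  }
  if (is.unsorted(x)) stop("x must be sorted ascending", call. = FALSE)
  if (diff(range(x)) == 0) stop("degenerate x: all values equal", call. = FALSE)

  seg_fit <- function(xs, ys) {
    # closed-form simple OLS; returns c(intercept, slope, rss)
    mx <- mean(xs); my <- mean(ys)
    sxx <- sum((xs - mx)^2)
    b <- if (sxx == 0) 0 else sum((xs - mx) * (ys - my)) / sxx
    a <- my - b * mx
    resid <- ys - (a + b * xs)
    c(a, b, sum(resid^2))
  }

  best <- NULL
  for (i in seq(min_seg, n - min_seg)) {
    lo <- seg_fit(x[1:i], y[1:i])
    hi <- seg_fit(x[(i + 1):n], y[(i + 1):n])
    rss <- lo[3] + hi[3]
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(i = i, lo = lo, hi = hi, rss = rss)
    }
  }
  structure(
    list(bp_x = x[best$i + 1],   # first point governed by the upper segment
         slope_lo = best$lo[2], slope_hi = best$hi[2],
         intercept_lo = best$lo[1], intercept_hi = best$hi[1],
         rss = best$rss, n_lo = best$i, n_hi = n - best$i),
    class = "breakpoint_fit"
  )
}

# Time at which a (noisy, rising) channel first reaches `level`, read off a
# 3-bin running mean to damp first-passage bias from bin noise.
.first_passage <- function(t, v, level) {
  vs <- .running_mean(v, 1L)
  i <- which(vs >= level)[1]
  if (is.na(i)) return(t[length(t)])
  t[i]
}

# Bins eligible for threshold search: ramp phase minus its first minute.
ramp_search_bins <- function(binned, skip_first_s = 60) {
  protocol <- attr(binned, "protocol")
  t0 <- ramp_start(protocol) + skip_first_s
  keep <- binned$phase == "ramp" & binned$t_mid >= t0
  binned[keep, , drop = FALSE]
}

# Slope of v against t over bins with t_mid in [t_from, t_from + span_s].
.window_slope <- function(t, v, t_from, span_s) {
  in_win <- t >= t_from & t <= t_from + span_s
  if (sum(in_win) < 3) return(NA_real_)
  tt <- t[in_win]; vv <- v[in_win]
  sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
}

# Centred running mean over (2*half + 1) bins, truncated at the edges.
.running_mean <- function(v, half = 2L) {
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# Nadir-plus-sustained-rise search over a ventilatory-equivalent ratio.
# The nadir region of a ventilatory-equivalent curve is flat, so a pointwise
# global minimum is noise-fragile; instead the search is anchored within
# +/- anchor_halfwin (default 30 s, matching the adjudication tolerance) of
# the secondary-criterion breakpoint time and the
# nadir is the minimum of a 5-bin running mean of the ratio there. The
# candidate must sit past a declining approach (the ratio may not have risen
# by more than 8% of its level over the preceding 90 s), must be followed by
# a sustained rise (positive raw-ratio slope over sustain_s), and a guard
# ratio (VE/VCO2 during the aerobic-threshold search), if given, must not
# rise by more than 10% of its level over the same span.
.find_nadir <- function(binned, ratio, t_anchor, guard = NULL,
                        sustain_s = 60, anchor_halfwin = 30) {
  t <- binned$t_mid
  n <- length(t)
  smoothed <- .running_mean(ratio, 2L)
  near <- which(abs(t - t_anchor) <= anchor_halfwin & t + 30 <= t[n])
  if (!length(near)) {
    stop("no bins near the secondary-criterion breakpoint", call. = FALSE)
  }
  i_sm <- near[order(smoothed[near], t[near])][1]
  # refine on the raw ratio: the running mean locates the basin but drags
  # the minimum early when the post-nadir rise is much steeper than the
  # approach; the raw minimum within +/- 2 bins restores it
  cand <- intersect((i_sm - 2L):(i_sm + 2L), seq_len(n))
  i <- cand[order(ratio[cand], t[cand])][1]
  lvl <- smoothed[i_sm]
  pre_from <- max(t[1], t[i] - 90)
  pre_span <- t[i] - pre_from
  pre <- .window_slope(t, smoothed, pre_from, pre_span)
  if (i <= 2 || (!is.na(pre) && pre * pre_span > 0.08 * lvl)) {
    stop("no qualifying ventilatory-equivalent nadir: ratio rising on approach",
         call. = FALSE)
  }
  post <- .window_slope(t, ratio, t[i], sustain_s)
  if (is.na(post) || post <= 0) {
    stop("ventilatory-equivalent rise after the nadir is not sustained", call. = FALSE)
  }
  if (!is.null(guard)) {
    gsl <- .window_slope(t, guard, t[i], sustain_s)
    g_lvl <- mean(guard[t >= t[i] & t <= t[i] + sustain_s])
    if (!is.na(gsl) && gsl * sustain_s > 0.10 * g_lvl) {
      stop("VE/VCO2 already rising at the candidate nadir: not an aerobic threshold",
           call. = FALSE)
    }
  }
  i
}

.colocated <- function(binned, t_at) {
  list(hr = rolling_value_at(binned, t_at, variable = "hr"),
       rer = rolling_value_at(binned, t_at, variable = "rer"),
       power = rolling_value_at(binned, t_at, variable = "power"),
       ve = rolling_value_at(binned, t_at, variable = "ve"))
}

.threshold_result <- function(binned, t_primary, t_secondary,
                              method_primary, method_secondary, label) {
  agreement <- abs(t_primary - t_secondary)
  structure(
    list(label = label, t = t_primary, t_secondary = t_secondary,
         agreement_s = agreement, flagged = is.finite(agreement) && agreement > 30,
         vo2_30s = rolling_value_at(binned, t_primary, variable = "vo2"),
         method_primary = method_primary, method_secondary = method_secondary,
         co_located = .colocated(binned, t_primary)),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<%s> t = %g s, VO2(30s) = %.0f mL/min [%s vs %s, |dt| = %g s%s]\n",
              x$label, x$t, x$vo2_30s, x$method_primary, x$method_secondary,
              x$agreement_s, if (isTRUE(x$flagged)) ", FLAGGED > 30 s" else ""))
  invisible(x)
}

#' Detect the aerobic (first ventilatory) threshold
#'
#' Primary criterion: the nadir of the ventilatory equivalent for oxygen
#' (VE/VO2) within the ramp phase (first ramp minute excluded), followed by
#' a sustained rise of VE/VO2 over the next 60 s while VE/VCO2 is still
#' non-increasing. Secondary criterion: the V-slope breakpoint of VCO2
#' against VO2, reported as the time VO2 first reaches the breakpoint
#' abscissa. The result carries the primary time; if the two criteria
#' disagree by more than 30 s the result is flagged for review rather than
#' rejected.
#'
#' @param binned A `binned_series` containing a ramp phase of at least 3 min.
#' @param sustain_s Sustained-rise window, seconds.
#' @return A `threshold_result` with the landmark time, its 30-s VO2 and
#'   co-located HR, RER, power and VE.
#' @export
detect_aert <- function(binned, sustain_s = 60) {
  search <- ramp_search_bins(binned)
  if (nrow(search) < 12) stop("ramp phase too short for threshold detection", call. = FALSE)
  o <- order(search$vo2)
  bp <- piecewise_breakpoint(search$vo2[o], search$vco2[o])
  t_secondary <- .first_passage(search$t_mid, search$vo2, bp$bp_x)
  i <- .find_nadir(search, ratio = search$ve / search$vo2 * 1000,
                   t_anchor = t_secondary,
                   guard = search$ve / search$vco2 * 1000, sustain_s = sustain_s)
  t_primary <- search$t_mid[i]
  .threshold_result(binned, t_primary, t_secondary,
                    "ve_vo2_nadir", "v_slope", "AerT")
}

#' Detect the anaerobic threshold (respiratory compensation point)
#'
#' Primary criterion: the nadir of the ventilatory equivalent for carbon
#' dioxide (VE/VCO2) in the ramp phase followed by a sustained rise over the
#' next 60 s. Secondary criterion: the breakpoint of VE against VCO2.
#' When an aerobic-threshold result is supplied, the ordering
#' t(AnT) > t(AerT) is enforced.
#'
#' @param binned A `binned_series`.
#' @param aert Optional `threshold_result` from [detect_aert()] used to check
#'   landmark ordering.
#' @param sustain_s Sustained-rise window, seconds.
#' @return A `threshold_result`.
#' @export
detect_ant <- function(binned, aert = NULL, sustain_s = 60) {
  search <- ramp_search_bins(binned)
  if (nrow(search) < 12) stop("ramp phase too short for threshold detection", call. = FALSE)
  o <- order(search$vco2)
  bp <- piecewise_breakpoint(search$vco2[o], search$ve[o])
  t_secondary <- .first_passage(search$t_mid, search$vco2, bp$bp_x)
  i <- .find_nadir(search, ratio = search$ve / search$vco2 * 1000,
                   t_anchor = t_secondary, guard = NULL, sustain_s = sustain_s)
  t_primary <- search$t_mid[i]
  res <- .threshold_result(binned, t_primary, t_secondary,
                           "ve_vco2_nadir", "ve_vs_vco2", "AnT")
  if (!is.null(aert) && res$t <= aert$t) {
    stop(sprintf("anaerobic threshold (t = %g s) not later than aerobic threshold (t = %g s)",
                 res$t, aert$t), call. = FALSE)
  }
  res
}

#' Time at which RER crosses a level
#'
#' Finds the first upward crossing of the respiratory exchange ratio through
#' `level` within the ramp phase that is sustained for at least 30 s, and
#' returns the linearly interpolated crossing time between the last bin
#' below and the first bin at or above the level.
#'
#' @param binned A `binned_series`.
#' @param level RER level (default 1.0).
#' @param sustain_s Time the series must stay at or above `level`, seconds.
#' @return Crossing time in seconds.
#' @export
rer_crossing <- function(binned, level = 1.0, sustain_s = 30) {
  ramp <- binned[binned$phase == "ramp", , drop = FALSE]
  t <- ramp$t_mid; rer <- ramp$rer
  n <- length(t)
  for (i in seq(2, n)) {
    if (rer[i] >= level && rer[i - 1] < level) {
      ahead <- t >= t[i] & t <= min(t[i] + sustain_s, t[n])
      if (all(rer[ahead] >= level)) {
        frac <- (level - rer[i - 1]) / (rer[i] - rer[i - 1])
        return(t[i - 1] + frac * (t[i] - t[i - 1]))
      }
    }
  }
  stop(sprintf("RER never sustains a crossing of %.2f within the ramp phase", level),
       call. = FALSE)
}

#' Detect peak VO2
#'
#' The peak is the maximum 30-s rolling VO2 mean among windows ending within
#' the final minute of exercise, matching the convention of taking the
#' 30-s average of the highest VO2 during the last minute of a graded test.
#'
#' @param binned A `binned_series`.
#' @return A `peak_result` with `t_end` (window end), `vo2peak_30s` and
#'   co-located HR, RER, power and VE from the same window.
#' @export
detect_peak <- function(binned) {
  ramp <- binned[binned$phase == "ramp", , drop = FALSE]
  if (nrow(ramp) == 0) stop("no ramp phase present", call. = FALSE)
  w <- attr(binned, "bin_width")
  t_end <- max(ramp$t_mid)
  t_ramp0 <- min(ramp$t_mid)
  if (t_end - t_ramp0 < 60 - w) stop("less than 60 s of exercise data", call. = FALSE)
  # candidate 30-s windows [a, a+30] with end inside the final 60 s
  ends <- ramp$t_mid[ramp$t_mid >= t_end - 60 + w / 2]
  best <- NULL
  for (e in ends) {
    in_win <- ramp$t_mid >= e - 30 & ramp$t_mid <= e
    if (sum(in_win) < 2) next
    m <- mean(ramp$vo2[in_win])
    if (is.null(best) || m > best$m) best <- list(e = e, m = m, in_win = in_win)
  }
  if (is.null(best)) stop("less than 60 s of exercise data", call. = FALSE)
  win <- ramp[best$in_win, , drop = FALSE]
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(
    list(t_end = best$e, vo2peak_30s = best$m,
         co_located = list(hr = mean_na(win$hr),
                           rer = mean(win$vco2) / mean(win$vo2),
                           power = mean_na(win$power), ve = mean(win$ve))),
    class = "peak_result"
  )
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak> VO2peak(30s) = %.0f mL/min at t = %g s\n",
              x$vo2peak_30s, x$t_end))
  invisible(x)
}
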