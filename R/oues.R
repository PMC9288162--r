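#' Haycock body surface area
#'
#' BSA (m^2) = 0.024265 * BM^0.5378 * H^0.3964 with body mass in kg and
#' height in cm.
#'
#' @param bm Body mass, kg.
#' @param height Height, cm.
#' @return Body surface area in m^2 (vectorised).
#' @export
bsa_haycock <- function(bm, height) {
  if (any(bm <= 0) || any(height <= 0)) {
    stop("body mass and height must be positive", call. = FALSE)
  }
  0.024265 * bm^0.5378 * height^0.3964
}

#' Derive a complete anthropometry record
#'
#' From body mass, height and either fat-free mass or percentage fat mass,
#' fills body composition, BMI (kg/m^2) and Haycock BSA. When both `ffm` and
#' `fm` are supplied their sum must match body mass within `tol_kg`.
#'
#' @param bm Body mass, kg.
#' @param height Height, cm.
#' @param ffm Fat-free mass, kg (give this or `pct_fm`).
#' @param pct_fm Percentage fat mass (0-100).
#' @param fm Fat mass, kg; optional consistency check against `bm - ffm`.
#' @param tol_kg Tolerance for the `bm = ffm + fm` check.
#' @return A list of class `anthropometry`: `bm`, `height`, `ffm`, `fm`,
#'   `pct_ffm`, `pct_fm`, `bmi`, `bsa`.
#' @export
derive_anthropometry <- function(bm, height, ffm = NULL, pct_fm = NULL,
                                 fm = NULL, tol_kg = 0.5) {
  if (bm <= 0 || height <= 0) stop("bm and height must be positive", call. = FALSE)
  if (is.null(ffm) && is.null(pct_fm)) {
    stop("supply one of `ffm` or `pct_fm`", call. = FALSE)
  }
  if (!is.null(ffm) && !is.null(pct_fm)) {
    stop("supply only one of `ffm` or `pct_fm`", call. = FALSE)
  }
  if (is.null(ffm)) {
    fm_derived <- bm * pct_fm / 100
    ffm <- bm - fm_derived
    fm <- if (is.null(fm)) fm_derived else fm
  } else if (is.null(fm)) {
    fm <- bm - ffm
  }
  if (abs(ffm + fm - bm) > tol_kg) {
    stop(sprintf("ffm + fm = %.2f kg inconsistent with bm = %.2f kg", ffm + fm, bm),
         call. = FALSE)
  }
  structure(
    list(bm = bm, height = height, ffm = ffm, fm = fm,
         pct_ffm = 100 * ffm / bm, pct_fm = 100 * fm / bm,
         bmi = bm / (height / 100)^2, bsa = bsa_haycock(bm, height)),
    class = "anthropometry"
  )
}

#' Detect a terminal VO2 plateau
#'
#' Scans 30-s sliding windows of the ramp phase and flags those whose local
#' VO2-versus-time slope falls below `frac` of the slope the ramp should
#' drive (`vo2_gain` mL·min⁻¹·W⁻¹ times the ramp rate). The terminal
#' contiguous run of flagged windows, if it spans at least `min_s` seconds,
#' is returned as the plateau region; otherwise `NULL` (absence is a valid
#' result).
#'
#' @param binned A `binned_series`.
#' @param protocol A [protocol_spec()]; defaults to the one stored on `binned`.
#' @param vo2_gain Expected aerobic cost of cycling, mL·min⁻¹·W⁻¹.
#' @param frac Fraction of the expected slope below which VO2 counts as flat.
#' @param min_s Minimum plateau duration, seconds.
#' @return `list(t_start, t_end)` or `NULL`.
#' @export
detect_plateau <- function(binned, protocol = attr(binned, "protocol"),
                           vo2_gain = 10.3, frac = 1 / 3, min_s = 30) {
  ramp <- binned[binned$phase == "ramp", , drop = FALSE]
  if (nrow(ramp) < 3) return(NULL)
  expected <- vo2_gain * protocol$ramp_w_per_min / 60   # mL/min per s
  t <- ramp$t_mid
  n <- nrow(ramp)
  flat <- logical(n)           # window starting at bin i: [t_i, t_i + 30]
  for (i in seq_len(n)) {
    sl <- .window_slope(t, ramp$vo2, t[i], 30)
    flat[i] <- !is.na(sl) && sl < frac * expected
  }
  full <- which(t + 30 <= t[n] + 1e-9)   # windows fully inside the data
  if (!length(full)) return(NULL)
  last_win <- max(full)
  if (!flat[last_win]) return(NULL)
  i0 <- last_win
  while (i0 > 1 && flat[i0 - 1]) i0 <- i0 - 1
  region <- list(t_start = t[i0], t_end = t[n])
  if (region$t_end - region$t_start + 30 < min_s) return(NULL)
  region
}

#' Select the OUES fitting window below a landmark
#'
#' Includes bins with midpoints from the end of the pre-exercise period plus
#' the first ramp minute (`rest_s + unloaded_s + 60` under the default
#' protocol) up to and including the landmark time. For the peak window a
#' detected VO2 plateau region is removed. Windows with fewer than 5 bins
#' are refused.
#'
#' @param binned A `binned_series`.
#' @param landmark_t Landmark time, seconds (threshold time or peak
#'   window end).
#' @param protocol A [protocol_spec()]; defaults to the one on `binned`.
#' @param plateau Optional plateau region from [detect_plateau()].
#' @param label Window label: `"aert"`, `"ant"` or `"peak"`.
#' @return A list of class `oues_window`: `points` (tibble of `ve`, `vo2`),
#'   `t_start`, `t_end`, `n`, `upper_landmark`, `excluded`.
#' @export
select_window <- function(binned, landmark_t, protocol = attr(binned, "protocol"),
                          plateau = NULL, label = "peak") {
  t0 <- ramp_start(protocol) + 60
  keep <- binned$t_mid >= t0 & binned$t_mid <= landmark_t
  excluded <- list(pre_exercise_s = ramp_start(protocol), first_ramp_min = 60,
                   plateau = plateau)
  if (!is.null(plateau)) {
    keep <- keep & binned$t_mid < plateau$t_start
  }
  pts <- binned[keep, c("ve", "vo2"), drop = FALSE]
  if (nrow(pts) < 5) {
    stop(sprintf("OUES window [%g, %g] holds only %d bins (need >= 5)",
                 t0, landmark_t, nrow(pts)), call. = FALSE)
  }
  structure(
    list(points = tibble::as_tibble(pts),
         t_start = t0, t_end = landmark_t, n = nrow(pts),
         upper_landmark = label, excluded = excluded),
    class = "oues_window"
  )
}

#' Fit the oxygen uptake efficiency slope
#'
#' Ordinary least squares of VO2 (mL·min⁻¹) on log10 of VE (L·min⁻¹):
#' VO2 = a·log10(VE) + b. The slope `a` is the OUES.
#'
#' @param window An `oues_window` from [select_window()], or any list/tibble
#'   with `ve` and `vo2` (a bare data frame is also accepted).
#' @return A list of class `oues_fit`: `a`, `b`, `r2_fit`, `n`, `log_base`,
#'   `window`, and (after [normalize_oues()]) `normalized`.
#' @export
fit_oues <- function(window) {
  pts <- if (inherits(window, "oues_window")) window$points else tibble::as_tibble(window)
  if (!all(c("ve", "vo2") %in% names(pts))) {
    stop("window must provide `ve` and `vo2`", call. = FALSE)
  }
  if (any(pts$ve <= 0)) stop("VE must be positive for the log transform", call. = FALSE)
  x <- log10(pts$ve)
  if (stats::var(x) == 0) stop("zero variance in log10(VE); cannot fit OUES", call. = FALSE)
  fit <- stats::lm(vo2 ~ x, data = data.frame(vo2 = pts$vo2, x = x))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((pts$vo2 - mean(pts$vo2))^2)
  structure(
    list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
         r2_fit = r2, n = nrow(pts), log_base = 10,
         window = if (inherits(window, "oues_window")) window else NULL,
         normalized = NULL),
    class = "oues_fit"
  )
}

#' Normalise an OUES fit by anthropometrics
#'
#' @param result An `oues_fit`.
#' @param anthro An `anthropometry` record.
#' @return The `oues_fit` with `normalized = list(per_bm, per_ffm, per_bsa)`.
#' @export
normalize_oues <- function(result, anthro) {
  stopifnot(inherits(result, "oues_fit"), inherits(anthro, "anthropometry"))
  result$normalized <- list(per_bm = result$a / anthro$bm,
                            per_ffm = result$a / anthro$ffm,
                            per_bsa = result$a / anthro$bsa)
  result
}

#' @export
print.oues_fit <- function(x, ...) {
  cat(sprintf("<oues_fit%s> a = %.1f mL/min per log10(L/min), b = %.1f, R2 = %.3f (n = %d)\n",
              if (!is.null(x$window)) paste0(" ", x$window$upper_landmark) else "",
              x$a, x$b, x$r2_fit, x$n))
  if (!is.null(x$normalized)) {
    cat(sprintf("  /BM %.1f | /FFM %.1f | /BSA %.1f\n", x$normalized$per_bm,
                x$normalized$per_ffm, x$normalized$per_bsa))
  }
  invisible(x)
}
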