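#' Ramp protocol specification
#'
#' Describes the graded cycle-ergometer protocol: a seated rest period,
#' unloaded (0 W) pedalling, then a continuous workload ramp. The default is
#' the 1-min rest / 1-min unloaded / 15-25 W per min ramp protocol commonly
#' used with adolescents and young adults.
#'
#' @param rest_s Rest-phase duration in seconds.
#' @param unloaded_s Unloaded-pedalling duration in seconds.
#' @param ramp_w_per_min Ramp rate in W per minute; typically 15, 20 or 25.
#' @param cadence_rpm Nominal pedalling cadence (informational).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(rest_s = 60, unloaded_s = 60,
                          ramp_w_per_min = 15, cadence_rpm = 65) {
  if (ramp_w_per_min <= 0) stop("`ramp_w_per_min` must be positive", call. = FALSE)
  if (rest_s < 0 || unloaded_s < 0) stop("phase durations must be non-negative", call. = FALSE)
  structure(
    list(rest_s = rest_s, unloaded_s = unloaded_s,
         ramp_w_per_min = ramp_w_per_min, cadence_rpm = cadence_rpm),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> rest %ds | unloaded %ds | ramp %g W/min (cadence %g rpm)\n",
              x$rest_s, x$unloaded_s, x$ramp_w_per_min, x$cadence_rpm))
  invisible(x)
}

#' Ramp start time of a protocol
#' @param protocol A [protocol_spec()].
#' @return Seconds from test start at which the workload ramp begins.
#' @export
ramp_start <- function(protocol) protocol$rest_s + protocol$unloaded_s

new_breath_series <- function(df, id = NA_character_, smoothing = 0L) {
  out <- tibble::as_tibble(df)
  attr(out, "participant_id") <- id
  attr(out, "smoothing") <- as.integer(smoothing)
  class(out) <- c("breath_series", class(out))
  out
}

#' Smoothing window applied to a breath series
#' @param series A `breath_series`.
#' @return Integer window size in breaths; 0 means raw.
#' @export
smoothing_window <- function(series) {
  w <- attr(series, "smoothing")
  if (is.null(w)) 0L else w
}

#' Construct a breath-by-breath series from vectors
#'
#' Canonical units: `t` seconds from test start, `vo2`/`vco2` mL·min⁻¹,
#' `ve` L·min⁻¹, `hr` beats·min⁻¹, `power` W. The respiratory exchange ratio
#' is always derived as `vco2/vo2`, never stored.
#'
#' @param t,vo2,vco2,ve Required channels (equal length).
#' @param hr,power,rpe Optional channels.
#' @param id Participant identifier.
#' @return A `breath_series` (a tibble with one row per breath).
#' @export
breath_series <- function(t, vo2, vco2, ve, hr = NULL, power = NULL,
                          rpe = NULL, id = NA_character_) {
  df <- tibble::tibble(t = as.numeric(t), vo2 = as.numeric(vo2),
                       vco2 = as.numeric(vco2), ve = as.numeric(ve))
  df$hr <- if (is.null(hr)) NA_real_ else as.numeric(hr)
  df$power <- if (is.null(power)) NA_real_ else as.numeric(power)
  df$rpe <- if (is.null(rpe)) NA_real_ else as.numeric(rpe)
  out <- new_breath_series(df, id = id, smoothing = 0L)
  validate_breath_series(out)
  out
}

validate_breath_series <- function(series) {
  if (nrow(series) == 0) stop("breath series is empty", call. = FALSE)
  for (col in c("t", "vo2", "vco2", "ve")) {
    if (anyNA(series[[col]])) {
      stop(sprintf("missing values in required channel '%s'", col), call. = FALSE)
    }
  }
  bad_t <- which(diff(series$t) <= 0)
  if (length(bad_t)) {
    stop(sprintf("breath timestamps not strictly increasing at row %d", bad_t[1] + 1L),
         call. = FALSE)
  }
  if (any(series$vo2 <= 0)) {
    stop(sprintf("non-positive VO2 at row %d", which(series$vo2 <= 0)[1]), call. = FALSE)
  }
  if (any(series$ve <= 0)) {
    stop(sprintf("non-positive VE at row %d", which(series$ve <= 0)[1]), call. = FALSE)
  }
  if (any(series$vco2 < 0)) {
    stop(sprintf("negative VCO2 at row %d", which(series$vco2 < 0)[1]), call. = FALSE)
  }
  invisible(series)
}

# unit tags accepted per channel; factors convert INTO canonical units
.unit_factors <- list(
  t    = c("s" = 1, "sec" = 1, "min" = 60),
  vo2  = c("mL/min" = 1, "ml/min" = 1, "L/min" = 1000, "l/min" = 1000),
  vco2 = c("mL/min" = 1, "ml/min" = 1, "L/min" = 1000, "l/min" = 1000),
  ve   = c("L/min" = 1, "l/min" = 1, "mL/min" = 1e-3, "ml/min" = 1e-3),
  hr   = c("bpm" = 1, "1/min" = 1),
  power = c("W" = 1, "watt" = 1)
)

#' Read a breath-by-breath table from delimited text
#'
#' Reads a CSV/TSV metabolic-cart export with a header row, renames columns
#' to the canonical channel names via `column_map`, converts declared units,
#' and validates the series (strictly increasing time, positive VO2 and VE).
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names to file
#'   column names, e.g. `c(t = "Time", vo2 = "VO2", vco2 = "VCO2", ve = "VE")`.
#'   `t`, `vo2`, `vco2` and `ve` are required; `hr`, `power`, `rpe` optional.
#' @param units Named character vector of unit tags per canonical channel,
#'   e.g. `c(ve = "mL/min")`. Defaults: t seconds, vo2/vco2 mL/min, ve L/min.
#' @param sep Field separator; `NULL` guesses from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param id Participant identifier stored on the series.
#' @return A `breath_series`.
#' @export
read_breath_table <- function(path, column_map, units = NULL, sep = NULL,
                              id = NA_character_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("t", "vo2", "vco2", "ve")
  missing_req <- setdiff(required, names(column_map))
  if (length(missing_req)) {
    stop(sprintf("column_map missing required channel(s): %s",
                 paste(missing_req, collapse = ", ")), call. = FALSE)
  }
  for (ch in names(column_map)) {
    src <- column_map[[ch]]
    if (!src %in% names(raw)) {
      stop(sprintf("column '%s' (mapped to channel '%s') not found in %s",
                   src, ch, basename(path)), call. = FALSE)
    }
  }
  get_chan <- function(ch) {
    if (!ch %in% names(column_map)) return(NULL)
    v <- as.numeric(raw[[column_map[[ch]]]])
    if (!is.null(units) && ch %in% names(units)) {
      tag <- units[[ch]]
      fac <- .unit_factors[[ch]][tag]
      if (is.null(fac) || is.na(fac)) {
        stop(sprintf("unknown unit tag '%s' for channel '%s'", tag, ch), call. = FALSE)
      }
      v <- v * fac
    }
    v
  }
  breath_series(t = get_chan("t"), vo2 = get_chan("vo2"), vco2 = get_chan("vco2"),
                ve = get_chan("ve"), hr = get_chan("hr"),
                power = get_chan("power"), rpe = get_chan("rpe"), id = id)
}

#' Six-breath moving-average smoothing
#'
#' Replaces each gas channel (VO2, VCO2, VE; HR too when present) by a
#' centred moving mean over `window_breaths` breaths. Edge breaths use the
#' truncated available window, so series length and timestamps are unchanged.
#' Smoothing a series twice is refused.
#'
#' @param series A raw `breath_series`.
#' @param window_breaths Window size in breaths (default 6).
#' @return The smoothed `breath_series` with its smoothing flag set.
#' @export
smooth_breaths <- function(series, window_breaths = 6L) {
  validate_breath_series(series)
  if (smoothing_window(series) > 0) {
    stop("series is already smoothed; refusing to smooth twice", call. = FALSE)
  }
  window_breaths <- as.integer(window_breaths)
  if (window_breaths < 1) stop("`window_breaths` must be >= 1", call. = FALSE)
  half_lo <- window_breaths %/% 2L          # even windows lean one breath back
  half_hi <- (window_breaths - 1L) %/% 2L
  n <- nrow(series)
  run_mean <- function(v) {
    if (all(is.na(v))) return(v)
    vapply(seq_len(n), function(i) {
      idx <- max(1L, i - half_lo):min(n, i + half_hi)
      mean(v[idx])
    }, numeric(1))
  }
  out <- series
  for (col in c("vo2", "vco2", "ve", "hr")) out[[col]] <- run_mean(series[[col]])
  attr(out, "smoothing") <- window_breaths
  out
}

#' Average a breath series into fixed-width time bins
#'
#' Bins are left-closed right-open intervals `[k*w, (k+1)*w)` aligned to
#' t = 0. Each bin holds the mean of the breaths falling in it; empty bins
#' are absent, never zero-filled. The bin RER is recomputed from the bin mean
#' VO2 and VCO2 (ratio of means). Bins are labelled with the protocol phase
#' of their midpoint: rest, unloaded, then ramp until the last breath.
#'
#' @param series A smoothed `breath_series`.
#' @param protocol A [protocol_spec()].
#' @param bin_width_s Bin width in seconds (default 10).
#' @return A `binned_series`: a tibble with columns `t_mid`, `vo2`, `vco2`,
#'   `ve`, `hr`, `power`, `rer`, `phase`, `n_breaths`.
#' @export
bin_time_average <- function(series, protocol, bin_width_s = 10) {
  validate_breath_series(series)
  w <- bin_width_s
  if (max(series$t) < w) stop("series shorter than one bin", call. = FALSE)
  bin_idx <- floor(series$t / w)
  groups <- split(seq_len(nrow(series)), bin_idx)
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  rows <- lapply(groups, function(ix) {
    tibble::tibble(
      t_mid = (bin_idx[ix[1]] + 0.5) * w,
      vo2 = mean(series$vo2[ix]), vco2 = mean(series$vco2[ix]),
      ve = mean(series$ve[ix]), hr = mean_na(series$hr[ix]),
      power = mean_na(series$power[ix]), n_breaths = length(ix)
    )
  })
  bins <- do.call(rbind, rows)
  bins <- bins[order(bins$t_mid), , drop = FALSE]
  bins$rer <- bins$vco2 / bins$vo2
  r0 <- protocol$rest_s
  r1 <- r0 + protocol$unloaded_s
  bins$phase <- ifelse(bins$t_mid < r0, "rest",
                       ifelse(bins$t_mid < r1, "unloaded", "ramp"))
  bins <- bins[, c("t_mid", "vo2", "vco2", "ve", "hr", "power", "rer",
                   "phase", "n_breaths")]
  out <- tibble::as_tibble(bins)
  attr(out, "bin_width") <- w
  attr(out, "protocol") <- protocol
  attr(out, "participant_id") <- attr(series, "participant_id")
  class(out) <- c("binned_series", class(out))
  out
}

#' Windowed mean of a binned channel around a time point
#'
#' Mean of `variable` over bins whose midpoints lie in
#' `[t_center - width_s/2, t_center + width_s/2]`. When the window would
#' extend past the end of the series it is anchored to the final `width_s`
#' of data instead, so landmark averages near test end stay well defined.
#'
#' @param binned A `binned_series`.
#' @param t_center Window centre, seconds.
#' @param width_s Window width, seconds (default 30).
#' @param variable Channel name (default `"vo2"`).
#' @return The windowed mean (a single number).
#' @export
rolling_value_at <- function(binned, t_center, width_s = 30, variable = "vo2") {
  if (!variable %in% names(binned)) {
    stop(sprintf("unknown channel '%s'", variable), call. = FALSE)
  }
  tm <- binned$t_mid
  if (t_center < min(tm) - width_s / 2 || t_center > max(tm) + width_s / 2) {
    stop("`t_center` outside the binned time range", call. = FALSE)
  }
  lo <- t_center - width_s / 2
  hi <- t_center + width_s / 2
  if (hi > max(tm)) {           # anchor to the last width_s of data
    hi <- max(tm)
    lo <- hi - width_s
  }
  in_win <- tm >= lo & tm <= hi
  if (!any(in_win)) stop("no bins inside the averaging window", call. = FALSE)
  mean(binned[[variable]][in_win], na.rm = TRUE)
}
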