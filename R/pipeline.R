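#' Process one participant end to end
#'
#' Runs the full reduction for a single CPET: six-breath smoothing, 10-s
#' binning with protocol phases, landmark detection (aerobic and anaerobic
#' thresholds, peak), plateau screening, OUES fits over the three windows
#' and anthropometric normalisation. Stage failures degrade the record (the
#' failing landmark and its OUES are dropped and the record is marked
#' incomplete) rather than aborting the run.
#'
#' @param series A raw `breath_series`.
#' @param anthro An `anthropometry` record.
#' @param protocol A [protocol_spec()].
#' @param smooth_window Breaths in the moving average.
#' @param bin_width_s Bin width, seconds.
#' @return A list of class `participant_record`: `binned`, `landmarks`
#'   (aert/ant/peak), `plateau`, `oues` (aert/ant/peak `oues_fit`s),
#'   `anthro`, `complete`, `errors` (named stage messages), `log`.
#' @export
run_participant <- function(series, anthro, protocol = protocol_spec(),
                            smooth_window = 6L, bin_width_s = 10) {
  errors <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      note("%s: FAILED (%s)", name, conditionMessage(e))
      NULL
    })
  }

  smoothed <- smooth_breaths(series, smooth_window)
  binned <- bin_time_average(smoothed, protocol, bin_width_s)
  note("reduced %d breaths to %d bins of %g s", nrow(series), nrow(binned), bin_width_s)

  aert <- try_stage("aert", detect_aert(binned))
  ant <- try_stage("ant", detect_ant(binned, aert = aert))
  peak <- try_stage("peak", detect_peak(binned))
  plateau <- try_stage("plateau", detect_plateau(binned, protocol))
  if (!is.null(aert)) note("AerT at t = %g s (VO2 %0.f), |primary - secondary| = %g s",
                           aert$t, aert$vo2_30s, aert$agreement_s)
  if (!is.null(ant)) note("AnT at t = %g s (VO2 %0.f)", ant$t, ant$vo2_30s)
  if (!is.null(peak)) note("peak window ends t = %g s (VO2 %0.f)", peak$t_end, peak$vo2peak_30s)
  if (!is.null(plateau)) note("VO2 plateau [%g, %g] s excluded from the peak window",
                              plateau$t_start, plateau$t_end)

  fit_at <- function(name, t_land, use_plateau = FALSE) {
    if (is.null(t_land)) return(NULL)
    try_stage(paste0("oues_", name), {
      win <- select_window(binned, t_land, protocol,
                           plateau = if (use_plateau) plateau else NULL,
                           label = name)
      normalize_oues(fit_oues(win), anthro)
    })
  }
  oues <- list(
    aert = fit_at("aert", if (is.null(aert)) NULL else aert$t),
    ant = fit_at("ant", if (is.null(ant)) NULL else ant$t),
    peak = fit_at("peak", if (is.null(peak)) NULL else peak$t_end, use_plateau = TRUE)
  )

  structure(
    list(id = attr(series, "participant_id"), binned = binned,
         landmarks = list(aert = aert, ant = ant, peak = peak),
         plateau = plateau, oues = oues, anthro = anthro,
         complete = length(errors) == 0, errors = errors, log = log),
    class = "participant_record"
  )
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record> %s (%s)\n",
              if (is.na(x$id)) "unnamed" else x$id,
              if (x$complete) "complete" else
                paste("incomplete:", paste(names(x$errors), collapse = ", "))))
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

# One row of the cohort table from a complete participant record.
.cohort_row <- function(rec) {
  lm_cols <- function(res, suffix) {
    if (is.null(res)) {
      return(stats::setNames(as.list(rep(NA_real_, 5)),
                             paste0(c("vo2_", "hr_", "rer_", "power_", "ve_"), suffix)))
    }
    vo2 <- if (inherits(res, "peak_result")) res$vo2peak_30s else res$vo2_30s
    stats::setNames(list(vo2, res$co_located$hr, res$co_located$rer,
                         res$co_located$power, res$co_located$ve),
                    paste0(c("vo2_", "hr_", "rer_", "power_", "ve_"), suffix))
  }
  oues_cols <- function(fit, suffix) {
    if (is.null(fit)) {
      return(stats::setNames(as.list(rep(NA_real_, 4)),
                             paste0("oues_", suffix, c("", "_bm", "_ffm", "_bsa"))))
    }
    stats::setNames(list(fit$a, fit$normalized$per_bm, fit$normalized$per_ffm,
                         fit$normalized$per_bsa),
                    paste0("oues_", suffix, c("", "_bm", "_ffm", "_bsa")))
  }
  a <- rec$anthro
  vals <- c(list(id = rec$id, bm = a$bm, height = a$height, ffm = a$ffm,
                 bsa = a$bsa, bmi = a$bmi, complete = rec$complete),
            lm_cols(rec$landmarks$aert, "aert"),
            lm_cols(rec$landmarks$ant, "ant"),
            lm_cols(rec$landmarks$peak, "peak"),
            oues_cols(rec$oues$aert, "aert"),
            oues_cols(rec$oues$ant, "ant"),
            oues_cols(rec$oues$peak, "peak"))
  tibble::as_tibble(vals)
}

#' Process a cohort and assemble the study tables
#'
#' Runs [run_participant()] over a cohort, keeps complete cases for the
#' inferential statistics, and assembles: the per-participant cohort table
#' (anthropometrics, landmark physiology, OUES in absolute and normalised
#' terms, landmark fractions of peak VO2); mean ± SD summaries of landmark
#' physiology and OUES; repeated-measures ANOVAs across the three OUES
#' windows per scaling; and the 8-row agreement table (peak vs each
#' submaximal window × 4 scalings).
#'
#' @param participants A list of `list(series, anthro)` (extra elements such
#'   as `truth`/`config` from [simulate_cohort()] are ignored), or a list of
#'   `participant_record`s.
#' @param protocol A [protocol_spec()] used when records must be computed.
#'   Per-participant protocols from `simulate_cohort()` output are honoured.
#' @return A list of class `cohort_result`: `cohort` (per-participant
#'   tibble), `records`, `landmark_summary`, `oues_summary`, `anova` (list
#'   per scaling), `agreement` (8-row tibble), `reports` (the underlying
#'   `agreement_report`s), `n`, `n_complete`.
#' @export
run_cohort <- function(participants, protocol = protocol_spec()) {
  records <- lapply(participants, function(p) {
    if (inherits(p, "participant_record")) return(p)
    proto <- if (!is.null(p$config)) p$config$protocol else protocol
    run_participant(p$series, p$anthro, proto)
  })
  cohort <- do.call(rbind, lapply(records, .cohort_row))
  cohort$frac_aert <- cohort$vo2_aert / cohort$vo2_peak
  cohort$frac_ant <- cohort$vo2_ant / cohort$vo2_peak

  complete <- cohort[cohort$complete, , drop = FALSE]
  if (nrow(complete) < 3) {
    stop(sprintf("only %d complete participant records (need >= 3)", nrow(complete)),
         call. = FALSE)
  }

  msd <- function(v) sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
  landmark_summary <- do.call(rbind, lapply(
    c("hr", "rer", "power", "vo2", "ve"),
    function(ch) tibble::tibble(
      variable = ch,
      aert = msd(complete[[paste0(ch, "_aert")]]),
      ant = msd(complete[[paste0(ch, "_ant")]]),
      peak = msd(complete[[paste0(ch, "_peak")]]))))

  scalings <- c(absolute = "", per_bm = "_bm", per_ffm = "_ffm", per_bsa = "_bsa")
  anova <- lapply(scalings, function(sfx) {
    m <- as.matrix(complete[, paste0("oues_", c("aert", "ant", "peak"), sfx)])
    colnames(m) <- c("aert", "ant", "peak")
    rm_anova_bonferroni(m)
  })
  oues_summary <- do.call(rbind, lapply(names(scalings), function(nm) {
    sfx <- scalings[[nm]]
    tibble::tibble(
      scaling = nm,
      aert = msd(complete[[paste0("oues_aert", sfx)]]),
      ant = msd(complete[[paste0("oues_ant", sfx)]]),
      peak = msd(complete[[paste0("oues_peak", sfx)]]),
      F = anova[[nm]]$F, partial_eta2 = anova[[nm]]$partial_eta2,
      p = anova[[nm]]$p)
  }))

  reports <- list()
  for (win in c("aert", "ant")) {
    for (nm in names(scalings)) {
      sfx <- scalings[[nm]]
      lbl <- sprintf("peak vs %s (%s)", win, nm)
      reports[[lbl]] <- agreement_report(
        complete[[paste0("oues_peak", sfx)]],
        complete[[paste0("oues_", win, sfx)]], label = lbl)
    }
  }
  agreement <- do.call(rbind, lapply(reports, agreement_row))

  structure(
    list(cohort = cohort, records = records,
         landmark_summary = landmark_summary, oues_summary = oues_summary,
         anova = anova, agreement = agreement, reports = reports,
         n = nrow(cohort), n_complete = nrow(complete)),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d participants (%d complete)\n", x$n, x$n_complete))
  cat("\nOUES by window (mean ± SD):\n")
  print(as.data.frame(x$oues_summary), row.names = FALSE)
  cat("\nAgreement with peak OUES:\n")
  print(as.data.frame(x$agreement[, c("comparison", "r2", "slope", "mean_diff",
                                      "p", "te_pct", "icc")]), row.names = FALSE)
  invisible(x)
}
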