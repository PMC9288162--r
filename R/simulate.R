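#' Configuration for a synthetic CPET breath series
#'
#' Defines a ramp cycle test and the gas-exchange model used to generate it.
#' Two modes exist. `"loglinear"` inverts the OUES relation, VE =
#' 10^((VO2 - b)/a), so the true OUES is the configured `true_oues_a`
#' exactly. `"threephase"` builds VCO2 piecewise-linear against VO2 with a
#' knee at the injected aerobic threshold and VE piecewise-linear against
#' VCO2 with a knee at the injected anaerobic threshold, so the true
#' landmark locations are exact; its true OUES is defined as the fit to the
#' noiseless trace.
#'
#' Default physiology: resting VO2 5 mL·min⁻¹·kg⁻¹-equivalent supplied as
#' `vo2_rest`; aerobic cost of cycling 10.3 mL·min⁻¹·W⁻¹; thresholds at 53%
#' and 78% of peak VO2; RER 0.88 at and below the aerobic threshold and 1.02
#' at the anaerobic threshold (the peak RER then emerges from the VCO2
#' geometry, about 1.09 under defaults); ventilation 26.2 L per L VCO2 below
#' the respiratory compensation point, steepening by a factor 1.9 above it;
#' per-breath multiplicative noise with CV 0.05; breath intervals shrinking
#' linearly from 4 s to 1.5 s as ventilatory frequency rises.
#'
#' @param mode `"loglinear"` or `"threephase"`.
#' @param protocol A [protocol_spec()].
#' @param duration_s Total test duration (rest + unloaded + ramp), seconds.
#' @param vo2_rest Resting VO2, mL·min⁻¹.
#' @param vo2_gain Aerobic cost of cycling, mL·min⁻¹·W⁻¹.
#' @param tau_s First-order VO2 lag time constant onto the ramp, seconds.
#' @param true_oues_a,true_oues_b Log-linear OUES parameters (loglinear mode).
#' @param aert_frac,ant_frac Injected thresholds as fractions of peak VO2
#'   (threephase mode).
#' @param rer_start,rer_at_ant RER at/below the aerobic threshold and at the
#'   anaerobic threshold.
#' @param ve_per_vco2 VE-vs-VCO2 slope below the anaerobic threshold,
#'   L·min⁻¹ per L·min⁻¹.
#' @param ve_intercept VE at zero VCO2 on the lower segment, L·min⁻¹.
#' @param ve_slope_ratio Steepening factor of the VE-vs-VCO2 slope above the
#'   anaerobic threshold (must be >= 1.3).
#' @param hr_rest,hr_peak Heart-rate path endpoints, beats·min⁻¹.
#' @param noise_cv Per-breath multiplicative coefficient of variation
#'   applied independently to VO2, VCO2 and VE.
#' @param breath_interval Length-2 vector: breath interval at test start and
#'   end, seconds.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(mode = c("threephase", "loglinear"),
                             protocol = protocol_spec(ramp_w_per_min = 20),
                             duration_s = 840,
                             vo2_rest = 340, vo2_gain = 10.3, tau_s = 30,
                             true_oues_a = 3000, true_oues_b = -3300,
                             aert_frac = 0.53, ant_frac = 0.78,
                             rer_start = 0.88, rer_at_ant = 1.02,
                             ve_per_vco2 = 26.2, ve_intercept = 1.7,
                             ve_slope_ratio = 1.9,
                             hr_rest = 70, hr_peak = 186,
                             noise_cv = 0.05,
                             breath_interval = c(4, 1.5)) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, protocol = protocol, duration_s = duration_s,
              vo2_rest = vo2_rest, vo2_gain = vo2_gain, tau_s = tau_s,
              true_oues_a = true_oues_a, true_oues_b = true_oues_b,
              aert_frac = aert_frac, ant_frac = ant_frac,
              rer_start = rer_start, rer_at_ant = rer_at_ant,
              ve_per_vco2 = ve_per_vco2, ve_intercept = ve_intercept,
              ve_slope_ratio = ve_slope_ratio,
              hr_rest = hr_rest, hr_peak = hr_peak,
              noise_cv = noise_cv, breath_interval = breath_interval)
  if (!(aert_frac > 0 && aert_frac < ant_frac && ant_frac < 1)) {
    stop("need 0 < aert_frac < ant_frac < 1", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (ve_slope_ratio < 1.3) stop("ve_slope_ratio must be >= 1.3", call. = FALSE)
  if (any(c(vo2_rest, vo2_gain, hr_rest, hr_peak, breath_interval) <= 0)) {
    stop("physiological parameters must be positive", call. = FALSE)
  }
  if (duration_s <= ramp_start(protocol) + 180) {
    stop("duration leaves less than 3 min of ramp", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Noiseless VO2 at time t: rest level, then a lagged ramp response
# (first-order lag tau onto the linearly rising demand).
.vo2_noiseless <- function(t, cfg) {
  t0 <- ramp_start(cfg$protocol)
  rate <- cfg$vo2_gain * cfg$protocol$ramp_w_per_min / 60   # mL/min per s
  u <- pmax(t - t0, 0)
  cfg$vo2_rest + rate * (u - cfg$tau_s * (1 - exp(-u / cfg$tau_s)))
}

# Invert .vo2_noiseless for a VO2 target within the ramp (monotone).
.time_at_vo2 <- function(target, cfg) {
  f <- function(t) .vo2_noiseless(t, cfg) - target
  stats::uniroot(f, lower = ramp_start(cfg$protocol), upper = cfg$duration_s,
                 tol = 1e-6)$root
}

# Piecewise VCO2-vs-VO2 and VE-vs-VCO2 maps of the three-phase model.
.threephase_maps <- function(cfg, vo2_peak) {
  vo2_aert <- cfg$aert_frac * vo2_peak
  vo2_ant <- cfg$ant_frac * vo2_peak
  vco2_aert <- cfg$rer_start * vo2_aert
  s2 <- (cfg$rer_at_ant * vo2_ant - vco2_aert) / (vo2_ant - vo2_aert)
  if (s2 / cfg$rer_start < 1.3) {
    stop("VCO2-vs-VO2 slope ratio across the aerobic-threshold knee is < 1.3; ",
         "adjust rer_at_ant / aert_frac / ant_frac", call. = FALSE)
  }
  vco2_ant <- cfg$rer_at_ant * vo2_ant
  m1 <- cfg$ve_per_vco2
  m2 <- m1 * cfg$ve_slope_ratio
  ve_ant <- cfg$ve_intercept + m1 * vco2_ant / 1000
  list(
    vo2_aert = vo2_aert, vo2_ant = vo2_ant,
    vco2_of_vo2 = function(v) {
      ifelse(v <= vo2_aert, cfg$rer_start * v, vco2_aert + s2 * (v - vo2_aert))
    },
    ve_of_vco2 = function(c) {
      ifelse(c <= vco2_ant, cfg$ve_intercept + m1 * c / 1000,
             ve_ant + m2 * (c - vco2_ant) / 1000)
    }
  )
}

#' Simulate a breath-by-breath CPET
#'
#' Deterministic given `(config, seed)`. Returns the noisy breath series and
#' a ground-truth record holding the injected landmark times and values, the
#' true OUES and the noiseless per-breath trace.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed for the per-breath noise.
#' @param id Participant identifier stored on the series.
#' @return `list(series, truth)` where `series` is a `breath_series` and
#'   `truth` a list with `t_aert`, `t_ant`, `vo2_aert`, `vo2_ant`,
#'   `vo2_peak`, `t_end`, `oues_a`, `oues_b`, `noiseless`.
#' @export
simulate_cpet <- function(config, seed = 1L, id = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  cfg <- config
  # breath times: interval shrinks linearly with elapsed time
  t <- numeric(0); now <- cfg$breath_interval[1]
  while (now <= cfg$duration_s) {
    t <- c(t, now)
    frac <- now / cfg$duration_s
    now <- now + cfg$breath_interval[1] +
      frac * (cfg$breath_interval[2] - cfg$breath_interval[1])
  }
  n <- length(t)
  t0 <- ramp_start(cfg$protocol)
  power <- pmax(t - t0, 0) * cfg$protocol$ramp_w_per_min / 60
  vo2 <- .vo2_noiseless(t, cfg)
  vo2_peak <- .vo2_noiseless(cfg$duration_s, cfg)

  if (cfg$mode == "threephase") {
    maps <- .threephase_maps(cfg, vo2_peak)
    vco2 <- maps$vco2_of_vo2(vo2)
    ve <- maps$ve_of_vco2(vco2)
    t_aert <- .time_at_vo2(maps$vo2_aert, cfg)
    t_ant <- .time_at_vo2(maps$vo2_ant, cfg)
    truth_landmarks <- list(t_aert = t_aert, t_ant = t_ant,
                            vo2_aert = maps$vo2_aert, vo2_ant = maps$vo2_ant)
  } else {
    ve <- 10^((vo2 - cfg$true_oues_b) / cfg$true_oues_a)
    # RER rises linearly over the ramp so an RER crossing exists; VCO2 is
    # derived from it and carries no threshold structure in this mode
    rer <- ifelse(t <= t0, cfg$rer_start,
                  cfg$rer_start + (1.10 - cfg$rer_start) * (t - t0) /
                    (cfg$duration_s - t0))
    vco2 <- vo2 * rer
    truth_landmarks <- list(t_aert = NA_real_, t_ant = NA_real_,
                            vo2_aert = NA_real_, vo2_ant = NA_real_)
  }
  hr <- cfg$hr_rest + (cfg$hr_peak - cfg$hr_rest) * t / cfg$duration_s

  noiseless <- tibble::tibble(t = t, vo2 = vo2, vco2 = vco2, ve = ve,
                              hr = hr, power = power)
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    jitter <- function(v) v * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    vo2 <- jitter(vo2); vco2 <- jitter(vco2); ve <- jitter(ve)
  }
  series <- breath_series(t = t, vo2 = vo2, vco2 = vco2, ve = ve,
                          hr = hr, power = power, id = id)

  # true OUES: configured (loglinear) or fitted to the noiseless trace over
  # the standard window (pre-exercise + first ramp minute excluded)
  if (cfg$mode == "loglinear") {
    oues_a <- cfg$true_oues_a; oues_b <- cfg$true_oues_b
  } else {
    in_win <- t >= t0 + 60
    fit <- fit_oues(tibble::tibble(ve = noiseless$ve[in_win],
                                   vo2 = noiseless$vo2[in_win]))
    oues_a <- fit$a; oues_b <- fit$b
  }
  truth <- c(truth_landmarks,
             list(vo2_peak = vo2_peak, t_end = cfg$duration_s,
                  oues_a = oues_a, oues_b = oues_b, noiseless = noiseless))
  list(series = series, truth = truth)
}

# Deterministic truncated-normal draws via the inverse CDF.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a CPET cohort with anthropometrics
#'
#' Draws per-participant body size, fitness and threshold placement from
#' truncated normal distributions calibrated to a healthy young-male cohort
#' (body mass 68.0 ± 11.4 kg, height 176.3 ± 7.0 cm, fat mass 16.9 ± 5.2%,
#' peak VO2 43.8 ± 7.3 mL·min⁻¹·kg⁻¹, thresholds at 53 ± 9% and 78 ± 9% of
#' peak VO2), assigns a 15/20/25 W·min⁻¹ ramp, and simulates each test with
#' [simulate_cpet()]. Ventilatory efficiency (`ve_per_vco2`) is also drawn
#' per participant so that OUES varies beyond body-size scaling.
#'
#' @param n Number of participants.
#' @param seed Integer seed (drives both parameter draws and breath noise).
#' @param mode Generator mode passed to [synthetic_config()].
#' @param noise_cv Per-breath noise CV.
#' @return A list of `n` elements, each `list(series, anthro, truth, config)`.
#' @export
simulate_cohort <- function(n, seed = 1L, mode = "threephase", noise_cv = 0.05) {
  stopifnot(n >= 1)
  set.seed(seed)
  draws <- tibble::tibble(
    bm = rnorm_trunc(n, 68.0, 11.4, 48, 98),
    height = rnorm_trunc(n, 176.3, 7.0, 158, 196),
    pct_fm = rnorm_trunc(n, 16.9, 5.2, 6, 30),
    vo2peak_bm = rnorm_trunc(n, 43.8, 7.3, 28, 64),
    aert_frac = rnorm_trunc(n, 0.53, 0.09, 0.38, 0.66),
    ve_per_vco2 = rnorm_trunc(n, 26.2, 2.5, 20, 33),
    hr_peak = rnorm_trunc(n, 186, 10, 160, 205),
    ramp = sample(c(15, 20, 25), n, replace = TRUE),
    noise_seed = sample.int(1e6, n)
  )
  # upper truncation keeps the VCO2 knee slope ratio >= 1.3 (threephase)
  draws$ant_frac <- vapply(seq_len(n), function(i)
    rnorm_trunc(1, 0.78, 0.09, draws$aert_frac[i] + 0.08,
                min(0.90, 2.05 * draws$aert_frac[i])), numeric(1))

  lapply(seq_len(n), function(i) {
    d <- draws[i, ]
    vo2_rest <- 5 * d$bm
    vo2_peak <- d$vo2peak_bm * d$bm
    rate <- 10.3 * d$ramp / 60
    ramp_s <- (vo2_peak - vo2_rest) / rate + 30      # invert the lagged ramp
    cfg <- synthetic_config(
      mode = mode,
      protocol = protocol_spec(ramp_w_per_min = d$ramp),
      duration_s = 120 + ramp_s,
      vo2_rest = vo2_rest,
      aert_frac = d$aert_frac, ant_frac = d$ant_frac,
      ve_per_vco2 = d$ve_per_vco2,
      hr_peak = d$hr_peak, noise_cv = noise_cv
    )
    sim <- simulate_cpet(cfg, seed = d$noise_seed, id = sprintf("sim%03d", i))
    anthro <- derive_anthropometry(bm = d$bm, height = d$height, pct_fm = d$pct_fm)
    list(series = sim$series, anthro = anthro, truth = sim$truth, config = cfg)
  })
}

#' Synthetic stand-in for a per-participant OUES/VO2 cohort table
#'
#' Generates a cohort-level table of per-participant peak and submaximal
#' OUES, landmark VO2 values and anthropometrics by drawing from a
#' multivariate normal model calibrated to published cohort summary
#' statistics for healthy young males: OUES 2907 ± 656 (up to the aerobic
#' threshold), 3008 ± 575 (up to the anaerobic threshold) and 3022 ± 605
#' (peak), with peak-vs-submaximal correlations 0.566 and 0.927 (R² 0.32 and
#' 0.86); peak VO2 2961 ± 646 mL·min⁻¹ correlated 0.88 with peak OUES;
#' thresholds at 53 ± 9% and 78 ± 9% of peak VO2; body mass 68.0 ± 11.4 kg
#' (correlated 0.6 with peak VO2), height 176.3 ± 7.0 cm, fat mass
#' 16.9 ± 5.2%. The aerobic-vs-anaerobic OUES correlation is not published
#' and is set to 0.65.
#'
#' This is a synthetic stand-in, not measured data: it reproduces the
#' moments and correlation structure above, so statistics computed from it
#' check that the agreement battery recovers those published summaries from
#' data with the stated structure.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return A tibble with one row per participant: `id`, anthropometrics
#'   (`bm`, `height`, `ffm`, `bsa`), landmark VO2 (`vo2_aert`, `vo2_ant`,
#'   `vo2_peak`, mL·min⁻¹) and OUES columns, absolute and normalised
#'   (`oues_aert`, `oues_ant`, `oues_peak`, `*_bm`, `*_ffm`, `*_bsa`).
#' @export
simulate_reference_cohort <- function(n = 50, seed = 1L) {
  set.seed(seed)
  mu <- c(aert = 2907, ant = 3008, peak = 3022)
  sd <- c(aert = 656, ant = 575, peak = 605)
  r_pa <- sqrt(0.32); r_pn <- sqrt(0.86); r_an <- 0.65
  corr <- matrix(c(1, r_an, r_pa,
                   r_an, 1, r_pn,
                   r_pa, r_pn, 1), 3, 3)
  sigma <- diag(sd) %*% corr %*% diag(sd)
  z <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(sigma)
  oues <- sweep(z, 2, mu, "+")

  # peak VO2 conditional on peak OUES (r = 0.88), body mass conditional on
  # peak VO2 (r = 0.6); landmark VO2 via threshold fractions of peak VO2
  cond_norm <- function(x, mu_x, sd_x, mu_y, sd_y, r) {
    mu_y + r * sd_y / sd_x * (x - mu_x) +
      sqrt(1 - r^2) * sd_y * stats::rnorm(length(x))
  }
  vo2_peak <- cond_norm(oues[, 3], 3022, 605, 2961, 646, 0.88)
  vo2_peak <- pmax(vo2_peak, 1200)
  bm <- pmin(pmax(cond_norm(vo2_peak, 2961, 646, 68.0, 11.4, 0.6), 48), 98)
  height <- rnorm_trunc(n, 176.3, 7.0, 158, 196)
  pct_fm <- rnorm_trunc(n, 16.9, 5.2, 6, 30)
  aert_frac <- rnorm_trunc(n, 0.53, 0.09, 0.30, 0.72)
  ant_frac <- vapply(seq_len(n), function(i)
    rnorm_trunc(1, 0.78, 0.09, aert_frac[i] + 0.05, 0.95), numeric(1))

  ffm <- bm * (1 - pct_fm / 100)
  bsa <- bsa_haycock(bm, height)
  out <- tibble::tibble(
    id = sprintf("P%02d", seq_len(n)),
    bm = bm, height = height, ffm = ffm, bsa = bsa,
    vo2_aert = aert_frac * vo2_peak, vo2_ant = ant_frac * vo2_peak,
    vo2_peak = vo2_peak,
    oues_aert = oues[, 1], oues_ant = oues[, 2], oues_peak = oues[, 3]
  )
  for (w in c("aert", "ant", "peak")) {
    out[[paste0("oues_", w, "_bm")]] <- out[[paste0("oues_", w)]] / bm
    out[[paste0("oues_", w, "_ffm")]] <- out[[paste0("oues_", w)]] / ffm
    out[[paste0("oues_", w, "_bsa")]] <- out[[paste0("oues_", w)]] / bsa
  }
  out
}
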