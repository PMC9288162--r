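# Independent oracles: naive loop / definitional-formula implementations
# used to cross-check the package's vectorised or closed-form code paths.

oracle_moving_mean <- function(v, window) {
  n <- length(v)
  half_lo <- window %/% 2L
  half_hi <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (j in seq_len(n)) {
      if (j >= i - half_lo && j <= i + half_hi) { acc <- acc + v[j]; cnt <- cnt + 1 }
    }
    out[i] <- acc / cnt
  }
  out
}

oracle_bin_means <- function(t, v, width) {
  idx <- floor(t / width)
  out <- list()
  for (k in sort(unique(idx))) {
    sel <- idx == k
    out[[as.character(k)]] <- c(t_mid = (k + 0.5) * width, mean = mean(v[sel]))
  }
  do.call(rbind, out)
}

# exhaustive two-segment least squares via lm(); same tie-break (earlier
# breakpoint wins on equal rss)
oracle_breakpoint <- function(x, y, min_seg = 3) {
  n <- length(x)
  best <- NULL
  for (i in min_seg:(n - min_seg)) {
    f_lo <- stats::lm(y[1:i] ~ x[1:i])
    f_hi <- stats::lm(y[(i + 1):n] ~ x[(i + 1):n])
    rss <- sum(stats::resid(f_lo)^2) + sum(stats::resid(f_hi)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(i = i, rss = rss)
  }
  list(bp_x = x[best$i + 1], rss = best$rss)
}

oracle_ols <- function(x, y) {
  b <- stats::cov(x, y) / stats::var(x)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

oracle_te_pct <- function(x, y) {
  d <- x - y
  100 * (stats::sd(d) / sqrt(2)) / mean(c(x, y))
}

# ICC(3,1) via aov() mean squares (two-way, no interaction)
oracle_icc31 <- function(x, y) {
  n <- length(x)
  df <- data.frame(score = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   meth = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(score ~ subj + meth, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse)
}

# one-way repeated-measures ANOVA via aov() with an Error stratum
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(score = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   cond = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(score ~ cond + Error(subj/cond), data = df)
  tab <- summary(fit)[["Error: subj:cond"]][[1]]
  ss_cond <- tab["cond", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  list(F = tab["cond", "F value"], p = tab["cond", "Pr(>F)"],
       partial_eta2 = ss_cond / (ss_cond + ss_err))
}

# fabricate a binned_series directly (for fixtures where controlling bin
# values beats simulating breaths)
make_binned <- function(t_mid, vo2, vco2 = vo2 * 0.9, ve = vo2 / 40,
                        hr = 120, power = 100,
                        protocol = protocol_spec(), bin_width = 10) {
  n <- length(t_mid)
  rep_len2 <- function(v) rep_len(v, n)
  df <- tibble::tibble(t_mid = t_mid, vo2 = rep_len2(vo2), vco2 = rep_len2(vco2),
                       ve = rep_len2(ve), hr = rep_len2(hr),
                       power = rep_len2(power))
  df$rer <- df$vco2 / df$vo2
  r0 <- protocol$rest_s; r1 <- r0 + protocol$unloaded_s
  df$phase <- ifelse(df$t_mid < r0, "rest", ifelse(df$t_mid < r1, "unloaded", "ramp"))
  df$n_breaths <- 5L
  attr(df, "bin_width") <- bin_width
  attr(df, "protocol") <- protocol
  class(df) <- c("binned_series", class(df))
  df
}

# small noiseless three-phase simulation reduced to bins, reused across tests
noiseless_binned <- function(seed = 1, ...) {
  cfg <- synthetic_config(noise_cv = 0, ...)
  sim <- simulate_cpet(cfg, seed = seed)
  list(cfg = cfg, sim = sim,
       binned = bin_time_average(smooth_breaths(sim$series), cfg$protocol))
}
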