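test_that("Haycock BSA reproduces reference values and power-law scaling", {
  expect_equal(round(bsa_haycock(68.0, 176.3), 2), 1.82)
  expect_equal(bsa_haycock(1, 1), 0.024265)
  for (h in c(150, 176.3, 195)) {
    expect_equal(bsa_haycock(140, h) / bsa_haycock(70, h), 2^0.5378, tolerance = 1e-12)
  }
  expect_error(bsa_haycock(-1, 170), "positive")
})

test_that("derive_anthropometry fills and checks body composition", {
  a <- derive_anthropometry(bm = 80, height = 200, pct_fm = 20)
  expect_equal(a$bmi, 20.0)
  expect_equal(a$fm, 16); expect_equal(a$ffm, 64)
  expect_equal(a$pct_fm + a$pct_ffm, 100)

  a2 <- derive_anthropometry(bm = 68.0, height = 176.3, pct_fm = 16.9)
  expect_equal(a2$fm, 11.492, tolerance = 1e-3)
  expect_equal(a2$ffm, 56.508, tolerance = 1e-3)

  # measured FFM and FM summing to body mass are accepted
  a3 <- derive_anthropometry(bm = 68.0, height = 176.3, ffm = 56.3, fm = 11.7)
  expect_equal(a3$ffm, 56.3)
  # inconsistency beyond 0.5 kg is refused
  expect_error(derive_anthropometry(bm = 68.0, height = 176.3, ffm = 50, fm = 11.7),
               "inconsistent")
  expect_error(derive_anthropometry(bm = 68, height = 176), "ffm")
})

test_that("detect_plateau finds only genuine terminal flattening", {
  proto <- protocol_spec(ramp_w_per_min = 20)
  t_mid <- seq(125, 725, 10)
  expected <- 10.3 * 20 / 60
  # ramping at the expected slope throughout: no plateau
  vo2 <- 500 + expected * (t_mid - 120)
  expect_null(detect_plateau(make_binned(t_mid, vo2, protocol = proto), proto))
  # flat final 40 s
  vo2f <- vo2
  flat_from <- which(t_mid >= max(t_mid) - 40)
  vo2f[flat_from] <- vo2f[flat_from[1]]
  reg <- detect_plateau(make_binned(t_mid, vo2f, protocol = proto), proto)
  expect_false(is.null(reg))
  expect_gte(reg$t_start, max(t_mid) - 60)
  expect_equal(reg$t_end, max(t_mid))
  # smoothly decaying slope: boundary equals the first 30-s window whose
  # loop-oracle slope crosses expected/3
  decay <- pmin(1, exp(-(t_mid - 500) / 80))
  vo2d <- 500 + cumsum(c(0, diff(t_mid)) * expected * decay)
  bd <- make_binned(t_mid, vo2d, protocol = proto)
  regd <- detect_plateau(bd, proto)
  expect_false(is.null(regd))
  slope_at <- function(i) {
    sel <- t_mid >= t_mid[i] & t_mid <= t_mid[i] + 30
    stats::coef(stats::lm(vo2d[sel] ~ t_mid[sel]))[2]
  }
  full <- which(t_mid + 30 <= max(t_mid))
  flat_idx <- full[vapply(full, function(i) slope_at(i) < expected / 3, logical(1))]
  runs <- flat_idx[cumsum(c(1, diff(flat_idx) != 1)) ==
                     max(cumsum(c(1, diff(flat_idx) != 1)))]
  expect_equal(regd$t_start, t_mid[runs[1]])
})

test_that("select_window applies the standard exclusions", {
  t_mid <- seq(5, 695, 10)
  b <- make_binned(t_mid, vo2 = 400 + pmax(t_mid - 120, 0) * 3,
                   ve = 10 + pmax(t_mid - 100, 0) * 0.15)
  w <- select_window(b, landmark_t = 600)
  expect_equal(w$t_start, 180)
  expect_equal(w$t_end, 600)
  expect_equal(w$n, sum(t_mid >= 180 & t_mid <= 600))
  # degenerate short window is refused
  expect_error(select_window(b, landmark_t = 200), "need >= 5")
  # plateau bins are excluded from the peak window
  plat <- list(t_start = 620, t_end = 660)
  wp <- select_window(b, landmark_t = 660, plateau = plat)
  expect_equal(max(t_mid[t_mid >= 180 & t_mid <= 660 & t_mid < 620]),
               615)
  expect_equal(wp$n, sum(t_mid >= 180 & t_mid < 620))
})

test_that("window nesting holds across landmarks", {
  b <- make_binned(seq(5, 695, 10), vo2 = 1000, ve = 40)
  w1 <- select_window(b, 400, label = "aert")
  w2 <- select_window(b, 550, label = "ant")
  w3 <- select_window(b, 690, label = "peak")
  expect_lte(w1$n, w2$n); expect_lte(w2$n, w3$n)
  expect_true(all(utils::head(w2$points$ve, w1$n) == w1$points$ve))
})

test_that("fit_oues matches exact constructions and the closed-form oracle", {
  ve <- seq(20, 120, by = 10)
  w <- tibble::tibble(ve = ve, vo2 = 1000 * log10(ve) + 500)
  f <- fit_oues(w)
  expect_equal(f$a, 1000, tolerance = 1e-9)
  expect_equal(f$b, 500, tolerance = 1e-9)
  expect_equal(f$r2_fit, 1, tolerance = 1e-12)

  # a line through two distinct points is exact
  f2 <- fit_oues(tibble::tibble(ve = c(20, 80), vo2 = c(1200, 2600)))
  expect_equal(f2$a * log10(20) + f2$b, 1200, tolerance = 1e-9)
  expect_equal(f2$a * log10(80) + f2$b, 2600, tolerance = 1e-9)

  withr::with_seed(13, {
    for (rep in 1:20) {
      ve_r <- runif(30, 15, 130)
      vo2_r <- 2800 * log10(ve_r) + rnorm(30, 0, 150)
      fr <- fit_oues(tibble::tibble(ve = ve_r, vo2 = vo2_r))
      orc <- oracle_ols(log10(ve_r), vo2_r)
      expect_equal(fr$a, unname(orc["slope"]), tolerance = 1e-9)
      expect_equal(fr$b, unname(orc["intercept"]), tolerance = 1e-9)
    }
  })
  expect_error(fit_oues(tibble::tibble(ve = rep(50, 6), vo2 = 1:6)), "zero variance")
})

test_that("subsets of an exact log-linear relation give identical OUES", {
  b <- make_binned(seq(5, 695, 10), vo2 = NA, ve = NA)
  b$ve <- 8 + 0.16 * pmax(b$t_mid - 100, 1)
  b$vo2 <- 2800 * log10(b$ve) - 200
  a_vals <- vapply(c(350, 500, 690), function(lm_t)
    fit_oues(select_window(b, lm_t))$a, numeric(1))
  expect_equal(max(a_vals) - min(a_vals), 0, tolerance = 1e-9)
})

test_that("normalize_oues divides by the anthropometric denominators", {
  anthro <- derive_anthropometry(bm = 60, height = 170, pct_fm = 15)
  f <- fit_oues(tibble::tibble(ve = seq(20, 120, 10),
                               vo2 = 3000 * log10(seq(20, 120, 10)) + 100))
  fn <- normalize_oues(f, anthro)
  expect_equal(fn$normalized$per_bm, 3000 / 60, tolerance = 1e-9)
  expect_equal(fn$normalized$per_ffm, 3000 / anthro$ffm, tolerance = 1e-9)
  expect_equal(fn$normalized$per_bsa, 3000 / anthro$bsa, tolerance = 1e-9)
})

test_that("OUES estimation error shrinks with longer windows", {
  # log-linear simulations at a fixed seed grid: average |error| of the
  # fitted slope is non-increasing as the window grows
  errs <- matrix(NA_real_, nrow = 30, ncol = 3)
  lengths <- c(0.4, 0.7, 1.0)
  for (s in 1:30) {
    cfg <- synthetic_config(mode = "loglinear", noise_cv = 0.05)
    sim <- simulate_cpet(cfg, seed = 100 + s)
    b <- bin_time_average(smooth_breaths(sim$series), cfg$protocol)
    t_hi <- 180 + lengths * (max(b$t_mid) - 180)
    for (j in seq_along(t_hi)) {
      f <- fit_oues(select_window(b, t_hi[j]))
      errs[s, j] <- abs(f$a - sim$truth$oues_a)
    }
  }
  m <- colMeans(errs)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})
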