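test_that("Pearson banding follows the interval rule including the gap", {
  expect_equal(pearson_with_band(1:10, (1:10) * 2)$band, "very strong")
  expect_equal(pearson_with_band(1:10, 1:10)$r, 1)
  # construct samples with controlled r via mixing
  make_r <- function(target, n = 4000, seed = 3) {
    withr::with_seed(seed, {
      x <- rnorm(n); y <- target * x + sqrt(1 - target^2) * rnorm(n)
    })
    list(x = x, y = y)
  }
  s <- make_r(0.85)
  expect_equal(pearson_with_band(s$x, s$y)$band, "very strong")
  s2 <- make_r(0.55)
  r2 <- pearson_with_band(s2$x, s2$y)
  expect_true(r2$r > 0.5 && r2$r < 0.6)
  expect_equal(r2$band, "fair")     # documented mapping of the [0.5, 0.6) gap
  s3 <- make_r(0.1)
  expect_equal(pearson_with_band(s3$x, s3$y)$band, "poor")
  expect_error(pearson_with_band(rep(1, 5), 1:5), "zero variance")
})

test_that("OLP regression matches its defining formulas and flags biases", {
  x <- c(10, 12, 15, 18, 21, 25)
  f <- olp_regression(x, x)
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)
  expect_equal(f$slope_ci, c(1, 1)); expect_false(f$proportional_bias)
  expect_false(f$fixed_bias)

  f2 <- olp_regression(x, 2 * x + 3)
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 3)
  expect_true(f2$proportional_bias); expect_true(f2$fixed_bias)

  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(8:60, 1)
      xr <- rnorm(n, 100, 15)
      yr <- 0.9 * xr + rnorm(n, 5, 10)
      f3 <- olp_regression(xr, yr)
      r <- stats::cor(xr, yr)
      expect_equal(f3$slope, sign(r) * stats::sd(yr) / stats::sd(xr), tolerance = 1e-9)
      # algebraic identities: slope^2 = variance ratio; OLP = OLS slope / r;
      # the line passes through the bivariate mean
      expect_equal(f3$slope^2, stats::var(yr) / stats::var(xr), tolerance = 1e-9)
      ols <- unname(stats::coef(stats::lm(yr ~ xr))[2])
      expect_equal(f3$slope, ols / r, tolerance = 1e-9)
      expect_equal(mean(yr), f3$intercept + f3$slope * mean(xr), tolerance = 1e-9)
      expect_true(f3$slope_ci[1] <= f3$slope && f3$slope <= f3$slope_ci[2])
    }
  })
})

test_that("typical percentage error matches the definitional oracle", {
  expect_equal(typical_error_pct(c(100, 120, 140), c(100, 120, 140)), 0)
  expect_equal(typical_error_pct(c(100, 102), c(98, 100)), 0)  # constant diff
  withr::with_seed(29, {
    for (rep in 1:20) {
      x <- runif(25, 2000, 4000); y <- x + rnorm(25, -100, 200)
      expect_equal(typical_error_pct(x, y), oracle_te_pct(x, y), tolerance = 1e-9)
    }
  })
  expect_error(typical_error_pct(c(-10, -20, -30), c(10, 5, 15)), "positive")
})

test_that("ICC(3,1) matches the aov mean-squares oracle and its conventions", {
  x <- c(3, 5, 7, 9, 11, 14)
  r <- icc_consistency(x, x)
  expect_equal(r$icc, 1); expect_equal(r$band, "excellent")
  # consistency ICC ignores a fixed shift
  r2 <- icc_consistency(x, x + 5)
  expect_equal(r2$icc, 1, tolerance = 1e-12)
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(6:40, 1)
      subj <- rnorm(n, 3000, 500)
      xr <- subj + rnorm(n, 0, 200); yr <- subj + rnorm(n, -50, 200)
      ri <- icc_consistency(xr, yr)
      expect_equal(ri$icc, oracle_icc31(xr, yr), tolerance = 1e-9)
      expect_true(ri$ci[1] <= ri$icc && ri$icc <= ri$ci[2])
    }
  })
  expect_error(icc_consistency(rep(2, 6), rep(2, 6)), "undefined")
})

test_that("Bland-Altman percentage limits behave and calibrate", {
  x <- c(100, 110, 120, 130)
  b <- bland_altman_pct(x, x)
  expect_equal(c(b$mean_pct, b$lo, b$hi), c(0, 0, 0))
  withr::with_seed(41, {
    xr <- runif(40, 2500, 3500); yr <- xr * runif(40, 0.85, 1.15)
  })
  br <- bland_altman_pct(xr, yr)
  d <- 100 * (xr - yr) / ((xr + yr) / 2)
  expect_equal(br$mean_pct, mean(d), tolerance = 1e-12)
  expect_equal(br$hi - br$mean_pct, br$mean_pct - br$lo, tolerance = 1e-9)
  expect_equal(br$hi, mean(d) + 1.96 * stats::sd(d), tolerance = 1e-12)
  # limits contain about 95% of differences on a large normal sample
  withr::with_seed(43, {
    xb <- rnorm(10000, 3000, 300); yb <- xb + rnorm(10000, 20, 150)
  })
  bb <- bland_altman_pct(xb, yb)
  inside <- mean(bb$per_subject >= bb$lo & bb$per_subject <= bb$hi)
  expect_lt(abs(inside - 0.95), 0.02)
  expect_error(bland_altman_pct(c(5, -10, 5), c(5, 5, 5)), "non-positive")
})

test_that("paired t handles degenerate differences and matches the formula", {
  x <- c(3, 4, 5, 6)
  expect_equal(paired_t(x, x)$p, 1)
  expect_true(paired_t(x, x)$degenerate)
  expect_equal(paired_t(x, x + 2)$p, 0)
  withr::with_seed(47, {
    xr <- rnorm(20, 100, 10); yr <- xr + rnorm(20, 2, 5)
  })
  res <- paired_t(xr, yr)
  d <- xr - yr
  t_manual <- mean(d) / (stats::sd(d) / sqrt(20))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-abs(t_manual), 19), tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches the aov oracle and post hocs flag shifts", {
  m0 <- matrix(rep(c(10, 12, 14, 16, 19), 3), ncol = 3)
  r0 <- rm_anova_bonferroni(m0)
  expect_equal(r0$F, 0); expect_equal(r0$partial_eta2, 0)

  withr::with_seed(53, {
    for (rep in 1:10) {
      n <- sample(6:30, 1)
      m <- matrix(rnorm(n * 3, 3000, 400), ncol = 3) + rnorm(n, 0, 300)
      r <- rm_anova_bonferroni(m)
      orc <- oracle_rm_anova(m)
      expect_equal(r$F, orc$F, tolerance = 1e-9)
      expect_equal(r$p, orc$p, tolerance = 1e-9)
      expect_equal(r$partial_eta2, orc$partial_eta2, tolerance = 1e-9)
    }
  })

  withr::with_seed(59, {
    base <- rnorm(12, 3000, 50)
    m2 <- cbind(a = base + rnorm(12, 0, 30), b = base + rnorm(12, 0, 30),
                c = base + 800 + rnorm(12, 0, 30))
  })
  r2 <- rm_anova_bonferroni(m2)
  expect_lt(r2$pairwise$p_bonferroni[r2$pairwise$pair == "a vs c"], 0.05)
  expect_lt(r2$pairwise$p_bonferroni[r2$pairwise$pair == "b vs c"], 0.05)
  expect_gt(r2$pairwise$p_bonferroni[r2$pairwise$pair == "a vs b"], 0.05)
  expect_error(rm_anova_bonferroni(m2[1:2, ]), "at least 3")
})

test_that("agreement_report assembles the battery coherently", {
  x <- c(2800, 3000, 3200, 2600, 3400, 2900, 3100)
  rep_id <- agreement_report(x, x, label = "self")
  expect_equal(rep_id$r2, 1)
  expect_equal(rep_id$olp$slope, 1)
  expect_equal(rep_id$te_pct, 0)
  expect_equal(rep_id$icc, 1)
  expect_equal(c(rep_id$ba_lo_pct, rep_id$ba_hi_pct), c(0, 0))
  expect_equal(rep_id$mean_diff, 0)
  expect_equal(rep_id$p_paired_t, 1)

  withr::with_seed(61, {
    peak <- rnorm(30, 3022, 605)
    sub <- 0.9 * peak + rnorm(30, 250, 180)
  })
  rp <- agreement_report(peak, sub, label = "x")
  expect_equal(rp$mean_diff, mean(sub - peak), tolerance = 1e-12)
  expect_equal(rp$diff_range, range(sub - peak))
  expect_equal(rp$te_pct, oracle_te_pct(peak, sub), tolerance = 1e-12)
  # permutation invariance over subjects
  perm <- sample(30)
  rp2 <- agreement_report(peak[perm], sub[perm], label = "x")
  for (fld in c("r2", "te_pct", "icc", "mean_diff", "ba_lo_pct", "ba_hi_pct",
                "p_paired_t")) {
    expect_equal(rp2[[fld]], rp[[fld]], tolerance = 1e-12)
  }
  row <- agreement_row(rp)
  expect_equal(nrow(row), 1)
  expect_equal(row$slope, rp$olp$slope)
})
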