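test_that("descriptives match the sort-and-index oracle", {
  expect_equal(descriptives(c(1, 2, 3), c(1, 2, 3))$grand[["median"]], 2)
  expect_equal(descriptives(c(1, 2), c(3, 4))$grand[["median"]], 2.5)

  set.seed(31)
  x <- rnorm(17)
  y <- rnorm(17)
  d <- descriptives(x, y)
  pooled <- c(x, y)
  expect_equal(d$t1[["q1"]], sort_index_quantile(x, 0.25))
  expect_equal(d$t2[["q3"]], sort_index_quantile(y, 0.75))
  expect_equal(d$grand[["median"]], sort_index_quantile(pooled, 0.5))
  expect_error(descriptives(numeric(0), numeric(0)), "empty")
})

test_that("Wilcoxon signed-rank: exact p equals full sign enumeration", {
  # all-positive differences, n = 3 -> p = 2/8
  w <- wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))
  expect_equal(w$p_value, 0.25)
  expect_identical(w$method, "exact")

  # symmetric differences -> p = 1
  expect_equal(wilcoxon_signed_rank(c(0, 0), c(1, -1))$p_value, 1)

  # zero differences dropped
  w0 <- wilcoxon_signed_rank(c(5, 1, 2, 3), c(5, 2, 4, 6))
  expect_identical(w0$n_used, 3L)
  expect_equal(w0$p_value, 0.25)

  # degenerate: all zero
  expect_warning(wd <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_equal(wd$p_value, 1)

  # random pairs (with ties in |d|) vs the 2^n enumeration oracle
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3, 4), n, replace = TRUE)
    w <- wilcoxon_signed_rank(rep(0, n), d)
    expect_equal(w$p_value, enumerate_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon approximation agrees with stats::wilcox.test above n = 25", {
  set.seed(12)
  t1 <- rnorm(40)
  t2 <- t1 + rnorm(40, 0.3)
  mine <- wilcoxon_signed_rank(t1, t2)
  ref <- stats::wilcox.test(t2, t1, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_identical(mine$method, "normal approximation")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$statistic, unname(ref$statistic))
})

test_that("Spearman correlation and its magnitude labels", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$r, 1)
  expect_equal(spearman_rho(1:5, 5:1)$r, -1)
  set.seed(3)
  x <- rnorm(20)
  y <- x + rnorm(20)
  expect_equal(spearman_rho(x, y)$r,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_rho(1:2, 2:1), "n >= 3")
  expect_identical(spearman_rho(x, y)$label %in%
                     c("low", "fair", "moderately strong", "very strong"),
                   TRUE)
})

test_that("variance components match hand ANOVA and aov()", {
  # worked 3 x 2 example: MSR = 8, MSC = 1.5, MSE = 0
  vc <- variance_components(c(1, 3, 5), c(2, 4, 6))
  expect_equal(vc$sigma2_p, 4)
  expect_equal(vc$sigma2_o, 0.5)
  expect_equal(vc$sigma2_res, 0)

  # identical columns with subject spread
  vc2 <- variance_components(c(1, 5, 9), c(1, 5, 9))
  expect_equal(vc2$sigma2_o, 0)
  expect_equal(vc2$sigma2_res, 0)
  expect_gt(vc2$sigma2_p, 0)

  # random data vs an independent sum-of-squares route (stats::aov)
  set.seed(88)
  t1 <- rnorm(12, 10, 3)
  t2 <- rnorm(12, 11, 3)
  vc3 <- variance_components(t1, t2)
  df <- data.frame(y = c(t1, t2),
                   subj = factor(rep(1:12, 2)),
                   occ = factor(rep(1:2, each = 12)))
  ms <- summary(stats::aov(y ~ subj + occ, data = df))[[1]][["Mean Sq"]]
  expect_equal(vc3$msr, ms[1], tolerance = 1e-10)
  expect_equal(vc3$msc, ms[2], tolerance = 1e-10)
  expect_equal(vc3$mse, ms[3], tolerance = 1e-10)

  expect_error(variance_components(1, 2), "n >= 2")
  expect_error(variance_components(c(1, NA), c(2, 3)), "complete")
})

test_that("agreement ICC: formula, frozen CI oracle, and properties", {
  # direct formula on the worked ANOVA example
  icc <- icc_agreement(variance_components(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(icc$icc, 4 / 4.5, tolerance = 1e-12)

  # perfect agreement components
  expect_equal(icc_agreement(make_variance_components(3, 0, 0))$icc, 1)

  # stated simulation target
  icc75 <- icc_agreement(make_variance_components(75, 5, 20))
  expect_equal(icc75$icc, 0.75)
  expect_identical(icc75$label, "substantial")

  # frozen oracle: pingouin ICC(A,1) on the shared fixture gives
  # ICC = 0.840083, CI [-0.02, 0.96] (two-decimal reporting)
  r <- icc_agreement(variance_components(fix_t1, fix_t2 + 2))
  expect_equal(r$icc, 0.840083, tolerance = 1e-6)
  expect_equal(round(r$ci, 2), c(-0.02, 0.96))

  # invariance under constant shift; monotone decrease in sigma2_o
  r1 <- icc_agreement(variance_components(fix_t1, fix_t2))
  r2 <- icc_agreement(variance_components(fix_t1 + 100, fix_t2 + 100))
  expect_equal(r1$icc, r2$icc, tolerance = 1e-9)
  base <- icc_agreement(make_variance_components(50, 5, 20))$icc
  inflated <- icc_agreement(make_variance_components(50, 25, 20))$icc
  expect_lt(inflated, base)

  expect_error(icc_agreement(make_variance_components(0, 0, 0)), "undefined")
})

test_that("SEM and SDC follow the agreement formulas", {
  expect_equal(sem_agreement(make_variance_components(1, 0.5, 0)),
               sqrt(0.5))
  expect_equal(sem_agreement(make_variance_components(4, 0, 0)), 0)
  # back-constructed to the published scale: sqrt(50 + 63.6) = 10.66
  expect_equal(sem_agreement(make_variance_components(10, 50, 63.6)),
               10.66, tolerance = 1e-3)

  expect_equal(smallest_detectable_change(0), 0)
  expect_equal(smallest_detectable_change(1), 1.96 * sqrt(2))
  # accepts a variance_components object directly
  expect_equal(smallest_detectable_change(make_variance_components(1, 0.5, 0)),
               1.96 * sqrt(2) * sqrt(0.5))
  expect_error(smallest_detectable_change(-1), "non-negative")
})

test_that("mean difference CI matches the closed-form t interval", {
  md <- mean_difference_ci(c(0, 0, 0), c(5, 5, 5))
  expect_equal(md$mean_diff, 5)
  expect_true(md$systematic)
  expect_equal(md$ci, c(5, 5))

  md2 <- mean_difference_ci(c(0, 0), c(1, -1))
  expect_false(md2$systematic)

  set.seed(14)
  t1 <- rnorm(25)
  t2 <- t1 + rnorm(25, 0.2)
  md3 <- mean_difference_ci(t1, t2)
  ref <- stats::t.test(t2 - t1)
  expect_equal(md3$ci, as.numeric(ref$conf.int), tolerance = 1e-12)
  expect_equal(md3$mean_diff, unname(ref$estimate), tolerance = 1e-12)
})

test_that("Bland-Altman bias, limits and proportional-bias slope", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, c(0, 0))

  bad <- bland_altman(c(1, 2, 3), c(4, 5, 6))
  expect_equal(bad$bias, 3)
  expect_equal(bad$loa, c(3, 3))

  set.seed(5)
  t1 <- rnorm(30)
  t2 <- t1 + rnorm(30, 0.4, 0.7)
  ba <- bland_altman(t1, t2)
  d <- t2 - t1
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa, mean(d) + c(-1.96, 1.96) * sd(d), tolerance = 1e-12)
  m <- (t1 + t2) / 2
  expect_equal(ba$prop_bias_slope, unname(coef(lm(d ~ m))[2]),
               tolerance = 1e-10)
})

test_that("reliability_report assembles per-variable rows and invariants", {
  coh <- small_cohort(n = 15, seed = 29, noise = 0.3)
  rep <- reliability_report(score_cohort(coh))
  expect_identical(nrow(rep), 4L)
  expect_setequal(rep$variable,
                  c("left knee up", "left knee down",
                    "right knee up", "right knee down"))
  # SDC / SEM is the constant 1.96 * sqrt(2) for every variable
  expect_equal(rep$sdc / rep$sem, rep(1.96 * sqrt(2), 4))
  expect_true(all(rep$icc >= 0 & rep$icc <= 1))
  expect_true(all(rep$icc_lo <= rep$icc_hi))
  ba <- attr(rep, "bland_altman")
  expect_identical(sort(names(ba)), sort(rep$variable))
})

test_that("systematic occasion shift drives Wilcoxon and the mean-diff flag", {
  coh <- generate_cohort(cohort_config(n_subjects = 25, occasion_shift = 8,
                                       sigma2_o = 1, sigma2_res = 4,
                                       sensor_noise_sd = 0, seed = 77))
  rep <- reliability_report(score_cohort(coh))
  expect_true(all(rep$wilcoxon_p < 0.05))
  expect_true(all(rep$systematic))
  expect_true(all(abs(abs(rep$mean_diff) - 8) < 2.5))
})
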