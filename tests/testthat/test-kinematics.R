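traj_df <- function(y, x = rep(0, length(y))) {
  data.frame(time_s = seq_along(y) / 30, knee_x_cm = x, knee_y_cm = y)
}

test_that("segment_phases splits at the first minimum", {
  v <- segment_phases(traj_df(c(0, -5, -10, -5, 0)))
  expect_identical(v$turning_index, 3L)
  expect_identical(nrow(v$down), 3L)
  expect_identical(nrow(v$up), 3L)

  # flat bottom: first-of-min rule
  f <- segment_phases(traj_df(c(0, -10, -10, 0)))
  expect_identical(f$turning_index, 2L)

  # degenerate inputs
  expect_error(segment_phases(traj_df(c(0, 1, 2, 3))), "turning point")
  expect_error(segment_phases(traj_df(c(0, -1, -2, -3))), "turning point")
  expect_error(segment_phases(traj_df(c(0, -1))), "samples")
  bad <- traj_df(c(0, -5, -10, -5, 0))
  bad$time_s <- rev(bad$time_s)
  expect_error(segment_phases(bad), "increasing")
})

test_that("compute_nta matches the arctangent oracle and sign convention", {
  # constant x -> zero angle, zero shift
  seg <- traj_df(seq(0, -10, length.out = 6), rep(2, 6))
  r <- compute_nta(seg, "left", "down")
  expect_equal(r$nta, 0)
  expect_equal(r$shift_cm, 0)

  # slope 0.1 cm/cm over 10 cm excursion -> |angle| = atan(0.1) = 5.71 deg,
  # |shift| = 1 cm
  y <- seq(0, -10, length.out = 11)
  medial_left <- traj_df(y, -0.1 * y)   # +x is medial for the left knee
  r <- compute_nta(medial_left, "left", "down")
  expect_equal(abs(r$nta), atan(0.1) * 180 / pi, tolerance = 1e-12)
  expect_equal(abs(r$nta), 5.71, tolerance = 1e-2)
  expect_equal(abs(r$shift_cm), 1.0, tolerance = 1e-12)
  expect_lt(r$nta, 0)  # medial left is negative in the reporting convention
  expect_equal(medial_displacement(r), abs(r$nta))

  # 1.8 cm of fitted-line travel over 7.80 cm excursion -> 13.0 deg
  y2 <- seq(0, -7.80, length.out = 20)
  r2 <- compute_nta(traj_df(y2, -(1.8 / 7.80) * y2), "right", "down")
  expect_equal(abs(r2$nta), atan(1.8 / 7.80) * 180 / pi, tolerance = 1e-12)
  expect_equal(abs(r2$nta), 13.0, tolerance = 0.01)
  # medial travel (+x) on a RIGHT knee is lateral -> negative nta... the
  # mirrored path is the medial one
  r2m <- compute_nta(traj_df(y2, (1.8 / 7.80) * y2), "right", "down")
  expect_gt(r2m$nta, 0)
  expect_equal(medial_displacement(r2m), abs(r2m$nta))

  # errors: zero excursion, too few samples
  expect_error(compute_nta(traj_df(rep(-5, 4), 1:4), "left", "down"),
               "excursion")
  expect_error(compute_nta(traj_df(-1, 0), "left", "down"), "samples")
})

test_that("medial_displacement applies the leg sign map", {
  expect_equal(medial_displacement(-6.34, "left"), 6.34)
  expect_equal(medial_displacement(13, "right"), 13)
  expect_equal(medial_displacement(4, "left"), -4)
  expect_equal(medial_displacement(c(-2, 5), c("left", "right")), c(2, 5))
  expect_error(medial_displacement(1, "middle"), "leg")
})

test_that("NTA invariances: scale, mirror, decimation, shift identity", {
  set.seed(202)
  for (i in 1:10) {
    slope <- runif(1, -0.4, 0.4)
    y <- seq(0, -runif(1, 5, 20), length.out = 25)
    x <- slope * y + rnorm(25, sd = 0.2)
    seg <- traj_df(y, x)
    r <- compute_nta(seg, "left", "down")

    # scale invariance
    rs <- compute_nta(traj_df(3.7 * y, 3.7 * x), "left", "down")
    expect_equal(rs$nta, r$nta, tolerance = 1e-12)

    # mirror antisymmetry + leg swap commutes
    rm <- compute_nta(traj_df(y, -x), "right", "down")
    expect_equal(rm$nta, -r$nta, tolerance = 1e-12)
    expect_equal(medial_displacement(rm), medial_displacement(r),
                 tolerance = 1e-12)

    # |shift| = tan(|angle|) * excursion
    expect_equal(abs(r$shift_cm),
                 tan(abs(r$nta) * pi / 180) * r$excursion_cm,
                 tolerance = 1e-12)

    # uniform decimation of a noiseless linear segment
    xl <- slope * y
    rfull <- compute_nta(traj_df(y, xl), "left", "down")
    rdec <- compute_nta(traj_df(y[seq(1, 25, by = 3)],
                                xl[seq(1, 25, by = 3)]), "left", "down")
    expect_equal(rdec$nta, rfull$nta, tolerance = 1e-9)
  }
})

test_that("scoring a noiseless cohort recovers the generating angles", {
  coh <- small_cohort(n = 8, seed = 17, noise = 0)
  scores <- score_cohort(coh)
  truth <- data.table::melt(coh$true_angles,
                            id.vars = c("subject", "leg", "occasion"),
                            measure.vars = c("true_down", "true_up"),
                            variable.name = "direction", value.name = "true")
  truth[, direction := ifelse(direction == "true_down", "down", "up")]
  m <- merge(scores, truth, by = c("subject", "leg", "occasion", "direction"))
  expect_identical(nrow(m), nrow(scores))
  expect_lt(max(abs(m$medial - m$true)), 1e-9)
})

test_that("filter_available reproduces the exclusion bookkeeping", {
  coh <- small_cohort(n = 5, seed = 23)
  scores <- score_cohort(coh)

  # no contamination -> availability 100%
  fa <- filter_available(scores, "reliability")
  expect_identical(fa$bookkeeping$availability_pct, 100)
  expect_identical(fa$bookkeeping$planned, 40L)  # 5 x 2 x 2 x 2

  # planned = available + sum(excluded) at every stage
  cc <- contaminate(coh, 0.25, 0.15, seed = 4)
  sc <- score_cohort(cc)
  for (purpose in c("reliability", "validity")) {
    bk <- filter_available(sc, purpose)$bookkeeping
    expect_identical(bk$available + sum(bk$excluded), bk$planned)
  }

  # pairwise deletion: a pair is dropped when either occasion is excluded
  bk_rel <- filter_available(sc, "reliability")
  pairs <- bk_rel$scores[, .N, by = .(subject, leg, direction)]
  expect_true(all(pairs$N == 2L))

  # validity purpose uses only way-down measures
  bk_val <- filter_available(sc, "validity")
  expect_true(all(bk_val$scores$direction == "down"))
})

test_that("availability percentages match the published bookkeeping", {
  # reliability arm: 296 planned measures, 32 easy-mode + 10 missing +
  # 1 improper excluded -> 85% available
  status <- rep("ok", 296)
  status[1:32] <- "easy_mode"
  status[33:42] <- "missing"
  status[43] <- "no_go"
  scores <- data.table::data.table(
    subject = rep(sprintf("S%03d", 1:37), each = 8),
    leg = rep(c("left", "right"), each = 4, times = 37),
    occasion = rep(rep(1:2, each = 2), times = 74),
    direction = rep(c("down", "up"), times = 148),
    status = sample(status), nta = 0, medial = 0, shift_cm = 0)
  bk <- filter_available(scores, "reliability")$bookkeeping
  expect_identical(bk$planned, 296L)
  expect_identical(sum(bk$excluded), 43L)
  expect_identical(bk$availability_pct, 85)

  # validity arm: 148 planned recordings, 15 easy-mode + 20 missing -> 76%
  vstatus <- rep("ok", 148)
  vstatus[1:15] <- "easy_mode"
  vstatus[16:35] <- "missing"
  vscores <- data.table::data.table(
    subject = rep(sprintf("S%03d", 1:37), each = 4),
    leg = rep(c("left", "right"), each = 2, times = 37),
    occasion = rep(1:2, times = 74),
    direction = "down",
    status = sample(vstatus), nta = 0, medial = 0, shift_cm = 0)
  bk2 <- filter_available(vscores, "validity")$bookkeeping
  expect_identical(bk2$planned, 148L)
  expect_identical(bk2$availability_pct, 76)
})
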