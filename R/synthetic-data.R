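# Synthetic single-leg-squat data with a known variance structure.
#
# The generator emulates a two-occasion movement-screening study: each
# subject squats on each leg on each occasion in front of a 30 Hz depth
# camera that reports the knee's frontal-plane position.  The "true"
# displacement angle of a recording follows a two-way random-effects
# decomposition (subject + occasion + residual) so that downstream ICC,
# SEM and SDC estimates have known targets.

#' Configuration for a synthetic SLS cohort
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults emulate
#' the published screening-study design this package targets: 37 subjects,
#' two legs, two occasions one week apart, 30 Hz sampling, and variance
#' components on the true displacement angle chosen so that the way-down
#' variables show an agreement ICC near 0.69 and an SEM near 10 degrees
#' (see the methods vignette for the derivation of the defaults).
#'
#' Angles use the internal *medial-positive* convention: a positive true
#' angle means the knee travels medially (toward the body midline) over the
#' phase, for either leg.  Conversion to the signed reporting convention
#' (negative = medial for the left knee, positive = medial for the right)
#' happens only when trajectories are scored.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param legs character subset of `c("left", "right")`.
#' @param occasions number of test occasions (>= 2 for reliability use).
#' @param sigma2_p between-subject variance of the true angle, deg^2.
#' @param sigma2_o between-occasion variance, deg^2 (drawn per
#'   subject-leg-occasion, not as a global shift).
#' @param sigma2_res residual variance, deg^2 (per measurement).
#' @param mean_angle_down,mean_angle_up population mean true angles for the
#'   descent and ascent phases, degrees, medial-positive.
#' @param occasion_shift systematic shift (degrees) added to every true
#'   angle on the second occasion; nonzero values create the
#'   Wilcoxon-positive scenario of a learning/systematic effect.
#' @param sensor_noise_sd i.i.d. Gaussian noise on the horizontal knee
#'   coordinate, cm.
#' @param squat_depth vertical excursion of the squat, cm.
#' @param samples_per_phase camera samples per phase (>= 2; 30 = one second
#'   of 30 Hz data per phase).
#' @param phase_duration_s duration of each phase in seconds.
#' @param rater_error_prob probability that a visual rater flips the true
#'   pass/fail label.
#' @param label_threshold degrees of way-down medial displacement at and
#'   beyond which the true state is "knee medial to foot" (fail).
#' @param easy_mode_rate,missing_rate per-recording contamination
#'   probabilities (must sum to at most 1).
#' @param seed integer seed making the whole cohort reproducible.
#' @return a `cohort_config` list, validated.
#' @examples
#' cfg <- cohort_config(n_subjects = 5, seed = 1)
#' @export
cohort_config <- function(n_subjects = 37,
                          legs = c("left", "right"),
                          occasions = 2,
                          sigma2_p = 216,
                          sigma2_o = 10,
                          sigma2_res = 87,
                          mean_angle_down = 2,
                          mean_angle_up = -3,
                          occasion_shift = 0,
                          sensor_noise_sd = 0.5,
                          squat_depth = 15,
                          samples_per_phase = 30,
                          phase_duration_s = 1,
                          rater_error_prob = 0.1,
                          label_threshold = 6,
                          easy_mode_rate = 0.11,
                          missing_rate = 0.04,
                          seed = NULL) {
  legs <- match.arg(legs, c("left", "right"), several.ok = TRUE)
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be >= 1", call. = FALSE)
  if (!is.numeric(occasions) || occasions < 1)
    stop("`occasions` must be >= 1", call. = FALSE)
  .check_nonneg(sigma2_p, "sigma2_p")
  .check_nonneg(sigma2_o, "sigma2_o")
  .check_nonneg(sigma2_res, "sigma2_res")
  .check_nonneg(sensor_noise_sd, "sensor_noise_sd")
  if (squat_depth <= 0) stop("`squat_depth` must be > 0", call. = FALSE)
  if (samples_per_phase < 2)
    stop("`samples_per_phase` must be >= 2", call. = FALSE)
  if (phase_duration_s <= 0)
    stop("`phase_duration_s` must be > 0", call. = FALSE)
  .check_prob(rater_error_prob, "rater_error_prob")
  .check_prob(easy_mode_rate, "easy_mode_rate")
  .check_prob(missing_rate, "missing_rate")
  if (easy_mode_rate + missing_rate > 1)
    stop("easy_mode_rate + missing_rate must be <= 1", call. = FALSE)
  if (!is.finite(label_threshold))
    stop("`label_threshold` must be finite", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), legs = legs,
    occasions = as.integer(occasions),
    sigma2_p = sigma2_p, sigma2_o = sigma2_o, sigma2_res = sigma2_res,
    mean_angle_down = mean_angle_down, mean_angle_up = mean_angle_up,
    occasion_shift = occasion_shift,
    sensor_noise_sd = sensor_noise_sd, squat_depth = squat_depth,
    samples_per_phase = as.integer(samples_per_phase),
    phase_duration_s = phase_duration_s,
    rater_error_prob = rater_error_prob,
    label_threshold = label_threshold,
    easy_mode_rate = easy_mode_rate, missing_rate = missing_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_config")
}

# internal: time/vertical profile shared by single and vectorised builders.
# Half-cosine per phase: smooth start and stop, a single global minimum at
# the turning point (shared sample), 2 * m - 1 samples in total.
.phase_profile <- function(depth, m, duration) {
  td <- seq(0, duration, length.out = m)
  tu <- seq(0, duration, length.out = m)[-1L]
  data.frame(
    time_s = c(td, duration + tu),
    y = c(-depth * (1 - cos(pi * td / duration)) / 2,
          -depth * (1 + cos(pi * tu / duration)) / 2),
    phase = c(rep("down", m), rep("up", m - 1L))
  )
}

# internal: horizontal path for given medial-positive angles and leg.
# Frame: knee_x positive toward the subject's right, so medial is +x for
# the left knee and -x for the right knee.
.leg_sign <- function(leg) ifelse(leg == "left", 1, -1)

.horizontal_path <- function(y, phase, depth, angle_down, angle_up, leg) {
  s <- .leg_sign(leg)
  td <- tanpi(angle_down / 180)
  tu <- tanpi(angle_up / 180)
  x_bottom <- s * td * depth
  ifelse(phase == "down", s * td * (-y), x_bottom + s * tu * (y + depth))
}

#' Generate one synthetic squat trajectory
#'
#' Builds a single 30 Hz-style frontal-plane knee path: the vertical
#' coordinate descends from 0 to `-depth` and returns along a half-cosine
#' per phase, and the horizontal coordinate travels
#' `tan(true_angle) * (vertical distance covered)` within each phase
#' (medial-positive angles), plus i.i.d. Gaussian sensor noise.
#'
#' @param true_angle_down,true_angle_up true displacement angles in degrees,
#'   medial-positive (positive = knee moves toward the midline during that
#'   phase).
#' @param depth squat depth in cm (> 0).
#' @param samples_per_phase samples per phase (>= 2); the turning-point
#'   sample is shared, so the trajectory has `2 * samples_per_phase - 1` rows.
#' @param noise_sd sd of Gaussian noise added to the horizontal coordinate, cm.
#' @param seed optional integer seed; fixing it makes the samples
#'   bit-identical across calls.
#' @param leg `"left"` or `"right"` (decides which x direction is medial).
#' @param phase_duration_s seconds per phase.
#' @param subject,occasion metadata carried on the trajectory.
#' @return an `sls_trajectory`: list with `subject`, `leg`, `occasion`,
#'   `status` (always `"ok"`) and `samples` (data.frame `time_s`,
#'   `knee_x_cm`, `knee_y_cm`).
#' @examples
#' tr <- generate_trajectory(5.71, -3, depth = 10, noise_sd = 0)
#' max(abs(tr$samples$knee_x_cm))  # ~ tan(5.71 deg) * 10 = 1 cm
#' @export
generate_trajectory <- function(true_angle_down, true_angle_up = 0,
                                depth = 15, samples_per_phase = 30,
                                noise_sd = 0, seed = NULL, leg = "left",
                                phase_duration_s = 1,
                                subject = "S1", occasion = 1L) {
  if (depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (samples_per_phase < 2)
    stop("`samples_per_phase` must be >= 2", call. = FALSE)
  leg <- match.arg(leg, c("left", "right"))
  if (!is.null(seed)) set.seed(seed)
  prof <- .phase_profile(depth, as.integer(samples_per_phase), phase_duration_s)
  x <- .horizontal_path(prof$y, prof$phase, depth,
                        true_angle_down, true_angle_up, leg)
  if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
  structure(list(
    subject = subject, leg = leg, occasion = as.integer(occasion),
    status = "ok",
    samples = data.frame(time_s = prof$time_s, knee_x_cm = x,
                         knee_y_cm = prof$y)
  ), class = "sls_trajectory")
}

#' Generate a two-occasion SLS cohort with known variance structure
#'
#' For every subject, leg and occasion the true displacement angle of each
#' phase is `mean + a + b + e` with `a ~ N(0, sigma2_p)` per subject-leg
#' (legs are treated as independent measures), `b ~ N(0, sigma2_o)` per
#' subject-leg-occasion, and `e ~ N(0, sigma2_res)` per phase measurement.
#' Trajectories are then generated from the true angles, and the
#' true-angle table is returned for parameter-recovery tests.
#'
#' @param config a [cohort_config()].
#' @return an `sls_cohort`: list with
#'   * `trajectories` — data.table `subject, leg, occasion, time_s,
#'     knee_x_cm, knee_y_cm`,
#'   * `recordings` — one row per subject/leg/occasion with `status`,
#'   * `true_angles` — data.table with medial-positive `true_down`,
#'     `true_up` per recording,
#'   * `config` — the configuration used.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 3, seed = 7))
#' nrow(coh$recordings)  # 3 subjects x 2 legs x 2 occasions = 12
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_subjects < 1) stop("empty cohort requested", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  subjects <- sprintf("S%03d", seq_len(config$n_subjects))
  key <- CJ(subject = subjects, leg = config$legs,
            occasion = seq_len(config$occasions), sorted = FALSE)
  setorder(key, subject, leg, occasion)

  # random effects, drawn in a fixed order for determinism
  sl <- unique(key[, .(subject, leg)])
  sl[, a := rnorm(.N, 0, sqrt(config$sigma2_p))]
  key <- sl[key, on = c("subject", "leg")]
  key[, b := rnorm(.N, 0, sqrt(config$sigma2_o))]
  key[, e_down := rnorm(.N, 0, sqrt(config$sigma2_res))]
  key[, e_up := rnorm(.N, 0, sqrt(config$sigma2_res))]
  key[, shift := ifelse(occasion == 2L, config$occasion_shift, 0)]
  key[, true_down := config$mean_angle_down + a + b + e_down + shift]
  key[, true_up := config$mean_angle_up + a + b + e_up + shift]

  true_angles <- key[, .(subject, leg, occasion, true_down, true_up)]

  # vectorised trajectory build: one profile replicated per recording
  prof <- .phase_profile(config$squat_depth, config$samples_per_phase,
                         config$phase_duration_s)
  npts <- nrow(prof)
  nrec <- nrow(true_angles)
  traj <- data.table(
    subject = rep(true_angles$subject, each = npts),
    leg = rep(true_angles$leg, each = npts),
    occasion = rep(true_angles$occasion, each = npts),
    time_s = rep(prof$time_s, nrec),
    knee_y_cm = rep(prof$y, nrec),
    phase = rep(prof$phase, nrec),
    true_down = rep(true_angles$true_down, each = npts),
    true_up = rep(true_angles$true_up, each = npts)
  )
  traj[, knee_x_cm := .horizontal_path(knee_y_cm, phase, config$squat_depth,
                                       true_down, true_up, leg)]
  if (config$sensor_noise_sd > 0)
    traj[, knee_x_cm := knee_x_cm + rnorm(.N, sd = config$sensor_noise_sd)]
  traj <- traj[, .(subject, leg, occasion, time_s, knee_x_cm, knee_y_cm)]

  recordings <- true_angles[, .(subject, leg, occasion)]
  recordings[, status := "ok"]

  structure(list(trajectories = traj, recordings = recordings,
                 true_angles = true_angles, config = config),
            class = "sls_cohort")
}

#' Contaminate a cohort with easy-mode and missing recordings
#'
#' Flags each recording independently as `easy_mode` (subject performed the
#' supported variant of the squat) or `missing` (the system reported no
#' value) with the given probabilities; remaining recordings stay `ok`.
#' Flags are deterministic for a fixed seed.
#'
#' @param cohort an `sls_cohort`.
#' @param easy_mode_rate,missing_rate probabilities in `[0, 1]` summing to
#'   at most 1; default to the cohort's config.
#' @param seed optional integer seed.
#' @return the cohort with updated `recordings$status` and a
#'   `status_counts` element (named counts summing to the number of
#'   recordings).
#' @export
contaminate <- function(cohort, easy_mode_rate = NULL, missing_rate = NULL,
                        seed = NULL) {
  stopifnot(inherits(cohort, "sls_cohort"))
  easy_mode_rate <- easy_mode_rate %||% cohort$config$easy_mode_rate
  missing_rate <- missing_rate %||% cohort$config$missing_rate
  .check_prob(easy_mode_rate, "easy_mode_rate")
  .check_prob(missing_rate, "missing_rate")
  if (easy_mode_rate + missing_rate > 1)
    stop("contamination rates must sum to <= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(nrow(cohort$recordings))
  new_status <- ifelse(u < easy_mode_rate, "easy_mode",
                       ifelse(u < easy_mode_rate + missing_rate,
                              "missing", "ok"))
  cohort$recordings <- copy(cohort$recordings)[, status := new_status]
  cohort$status_counts <- c(
    ok = sum(new_status == "ok"),
    easy_mode = sum(new_status == "easy_mode"),
    missing = sum(new_status == "missing"),
    no_go = sum(new_status == "no_go")
  )
  cohort
}

#' Simulate visual pass/fail ratings by two error-prone raters
#'
#' The true state of a recording is "fail" (knee medial to foot) when its
#' true way-down medial displacement is at or beyond `label_threshold`.
#' Each of two raters independently flips the true label with probability
#' `rater_error_prob`; disagreements are adjudicated by a third simulated
#' rater drawn from the same error model, mimicking a consensus procedure.
#'
#' @param true_angles the `true_angles` table of an `sls_cohort` (needs
#'   columns `subject`, `leg`, `occasion`, `true_down`).
#' @param label_threshold degrees; `true_down >= label_threshold` is a fail.
#' @param rater_error_prob per-rater flip probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return an `sls_ratings` data.table: `subject, leg, occasion, truth,
#'   rater1, rater2, consensus`, labels in `c("pass", "fail")`.
#' @export
generate_rater_labels <- function(true_angles, label_threshold = 6,
                                  rater_error_prob = 0.1, seed = NULL) {
  stopifnot(is.data.frame(true_angles),
            all(c("subject", "leg", "occasion", "true_down") %in%
                  names(true_angles)))
  if (!is.finite(label_threshold))
    stop("`label_threshold` must be finite", call. = FALSE)
  .check_prob(rater_error_prob, "rater_error_prob")
  if (!is.null(seed)) set.seed(seed)
  dt <- as.data.table(true_angles)[, .(subject, leg, occasion, true_down)]
  n <- nrow(dt)
  truth <- ifelse(dt$true_down >= label_threshold, "fail", "pass")
  flip <- function(lab, p) {
    f <- runif(length(lab)) < p
    ifelse(f, ifelse(lab == "fail", "pass", "fail"), lab)
  }
  r1 <- flip(truth, rater_error_prob)
  r2 <- flip(truth, rater_error_prob)
  r3 <- flip(truth, rater_error_prob)
  dt[, `:=`(truth = truth, rater1 = r1, rater2 = r2)]
  dt[, consensus := consensus_label(rater1, rater2, adjudicator = r3)]
  dt[, true_down := NULL]
  setattr(dt, "class", c("sls_ratings", class(dt)))
  dt[]
}

#' @export
print.sls_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic SLS cohort: %d subjects, legs {%s}, %d occasions (%d recordings)\n",
    x$config$n_subjects, paste(x$config$legs, collapse = ","),
    x$config$occasions, nrow(x$recordings)))
  st <- table(x$recordings$status)
  cat("Status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sls_trajectory <- function(x, ...) {
  cat(sprintf("SLS trajectory: subject %s, %s leg, occasion %d, %d samples [%s]\n",
              x$subject, x$leg, x$occasion, nrow(x$samples), x$status))
  invisible(x)
}
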