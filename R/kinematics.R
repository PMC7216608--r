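# Net-trajectory-angle (NTA) scoring of frontal-plane knee paths.
#
# A squat recording is split at its turning point (deepest sample) into a
# descent and an ascent phase.  Within a phase the knee's horizontal
# position is regressed on its vertical position (OLS); the NTA is the
# angle between that fitted "line of best fit" and the vertical axis,
# signed by the reporting convention used in screening reports:
# negative = medial displacement for the LEFT knee (lateral for the right),
# positive = medial for the RIGHT knee (lateral for the left).

#' Segment a squat into its descent and ascent phases
#'
#' The turning point is the first sample attaining the minimum vertical
#' coordinate ("first arrival at the bottom"); it is shared by both
#' segments.
#'
#' @param traj an `sls_trajectory`, or a data.frame with columns `time_s`,
#'   `knee_x_cm`, `knee_y_cm`.
#' @return list with `down` and `up` sample data.frames (both contain the
#'   turning-point row) and `turning_index` (index into the input rows).
#' @examples
#' tr <- generate_trajectory(5, depth = 10, noise_sd = 0)
#' seg <- segment_phases(tr)
#' @export
segment_phases <- function(traj) {
  s <- if (inherits(traj, "sls_trajectory")) traj$samples else as.data.frame(traj)
  stopifnot(all(c("time_s", "knee_x_cm", "knee_y_cm") %in% names(s)))
  n <- nrow(s)
  if (n < 3L)
    stop("segmentation needs at least 3 samples", call. = FALSE)
  if (any(diff(s$time_s) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  turn <- which.min(s$knee_y_cm)  # which.min takes the first of ties
  if (turn == 1L || turn == n)
    stop("no turning point: vertical coordinate is monotone", call. = FALSE)
  list(down = s[seq_len(turn), , drop = FALSE],
       up = s[turn:n, , drop = FALSE],
       turning_index = turn)
}

# internal: OLS fit of x on y over one phase segment
.fit_segment <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("segment needs at least 2 samples", call. = FALSE)
  dy <- y[n] - y[1L]
  excursion <- abs(dy)
  if (excursion == 0)
    stop("zero vertical excursion: angle undefined", call. = FALSE)
  vy <- var(y)
  if (vy == 0)
    stop("zero vertical excursion: angle undefined", call. = FALSE)
  slope <- cov(x, y) / vy          # cm horizontal per cm vertical
  x_travel <- slope * dy           # signed x travel of fitted line
  list(slope = slope, excursion = excursion, x_travel = x_travel)
}

#' Compute the net trajectory angle of one phase
#'
#' Fits `knee_x ~ knee_y` by ordinary least squares over the segment and
#' returns the angle of the fitted path against the vertical axis, mapped
#' to the signed reporting convention (negative = medial for the left
#' knee / lateral for the right; positive = medial for the right knee /
#' lateral for the left).  The net shift is the horizontal travel of the
#' fitted line over the phase's vertical excursion, with the same sign as
#' the angle.
#'
#' @param segment a phase segment from [segment_phases()] (data.frame with
#'   `knee_x_cm`, `knee_y_cm`).
#' @param leg `"left"` or `"right"` (metadata; the raw-angle sign already
#'   encodes the reporting convention in the x-positive-right frame).
#' @param direction `"down"` or `"up"`.
#' @return an `nta_result` list: `nta` (degrees, in `(-90, 90)`),
#'   `shift_cm`, `slope`, `excursion_cm`, `leg`, `direction`, `n`.
#' @examples
#' tr <- generate_trajectory(5.71, depth = 10, noise_sd = 0)
#' seg <- segment_phases(tr)
#' compute_nta(seg$down, leg = "left", direction = "down")$nta  # -5.71
#' @export
compute_nta <- function(segment, leg = "left",
                        direction = c("down", "up")) {
  leg <- match.arg(leg, c("left", "right"))
  direction <- match.arg(direction)
  seg <- as.data.frame(segment)
  stopifnot(all(c("knee_x_cm", "knee_y_cm") %in% names(seg)))
  fit <- .fit_segment(seg$knee_x_cm, seg$knee_y_cm)
  # reporting convention: nta = -atan(signed x travel / excursion);
  # medial travel is +x for the left knee, -x for the right, which makes
  # "negative = medial left, positive = medial right" hold for both phases
  nta <- -atan(fit$x_travel / fit$excursion) * 180 / pi
  shift <- tan(nta * pi / 180) * fit$excursion
  structure(list(nta = nta, shift_cm = shift, slope = fit$slope,
                 excursion_cm = fit$excursion, leg = leg,
                 direction = direction, n = nrow(seg)),
            class = "nta_result")
}

#' Convert a signed NTA to degrees of medial displacement
#'
#' Applies the leg sign map of the reporting convention: for the left knee
#' medial displacement is `-nta`, for the right knee `+nta`.  Positive
#' values mean the knee travelled medially (toward the midline), negative
#' values laterally; the magnitude always equals `|nta|`.
#'
#' @param nta an `nta_result`, or a numeric vector of signed NTA degrees.
#' @param leg `"left"` or `"right"`; vectorised when `nta` is numeric.
#'   Ignored (taken from the object) when `nta` is an `nta_result`.
#' @return numeric degrees of medial displacement (medial-positive).
#' @examples
#' medial_displacement(-6.34, leg = "left")  # 6.34 degrees medial
#' @export
medial_displacement <- function(nta, leg = NULL) {
  if (inherits(nta, "nta_result")) {
    leg <- nta$leg
    nta <- nta$nta
  }
  if (is.null(leg)) stop("`leg` is required for numeric input", call. = FALSE)
  if (!all(leg %in% c("left", "right")))
    stop("`leg` must be 'left' or 'right'", call. = FALSE)
  ifelse(leg == "left", -nta, nta)
}

#' Score every recording of a cohort
#'
#' Runs segmentation and NTA computation over all `ok` recordings and
#' returns a long score table with one row per recording and phase
#' direction.  Recordings with a non-`ok` status keep their status but get
#' `NA` scores.
#'
#' @param cohort an `sls_cohort`, or a trajectory data.table with columns
#'   `subject, leg, occasion, time_s, knee_x_cm, knee_y_cm` (all `ok`).
#' @return an `sls_scores` data.table: `subject, leg, occasion, direction,
#'   status, nta, medial, shift_cm` (angles in degrees; `medial` is
#'   medial-positive).
#' @export
score_cohort <- function(cohort) {
  if (inherits(cohort, "sls_cohort")) {
    traj <- cohort$trajectories
    rec <- cohort$recordings
  } else {
    traj <- as.data.table(cohort)
    rec <- unique(traj[, .(subject, leg, occasion)])
    rec[, status := "ok"]
  }
  stopifnot(all(c("subject", "leg", "occasion", "time_s",
                  "knee_x_cm", "knee_y_cm") %in% names(traj)))

  ok_rec <- rec[status == "ok"]
  tr <- traj[ok_rec[, .(subject, leg, occasion)],
             on = c("subject", "leg", "occasion")]
  setorder(tr, subject, leg, occasion, time_s)

  # phase assignment: first index of the minimum vertical coordinate
  tr[, idx := seq_len(.N), by = .(subject, leg, occasion)]
  tr[, turn := idx[which.min(knee_y_cm)], by = .(subject, leg, occasion)]
  down <- tr[idx <= turn]
  up <- tr[idx >= turn]

  fit_dt <- function(d, dir) {
    d[, {
      f <- .fit_segment(knee_x_cm, knee_y_cm)
      nta <- -atan(f$x_travel / f$excursion) * 180 / pi
      .(direction = dir, nta = nta,
        shift_cm = tan(nta * pi / 180) * f$excursion)
    }, by = .(subject, leg, occasion)]
  }
  scored <- rbind(fit_dt(down, "down"), fit_dt(up, "up"))

  # two rows (down/up) per planned recording, scored where available
  out <- rec[, .(direction = c("down", "up")),
             by = .(subject, leg, occasion, status)]
  out <- scored[out, on = c("subject", "leg", "occasion", "direction")]
  out[, medial := medial_displacement(nta, leg)]
  setcolorder(out, c("subject", "leg", "occasion", "direction", "status",
                     "nta", "medial", "shift_cm"))
  setorder(out, subject, leg, occasion, direction)
  setattr(out, "class", c("sls_scores", class(out)))
  out[]
}

#' Filter available measures and report exclusion bookkeeping
#'
#' Implements the study's exclusion rule: measures are dropped when the
#' recording is `easy_mode`, `missing`, or `no_go` (improper).  For the
#' reliability purpose, a variable's subject contributes only when both
#' occasions are available (pairwise deletion); for the validity purpose
#' only the way-down measure of each recording is used, deleted
#' per-recording.
#'
#' @param scores an `sls_scores` table (long: one row per recording and
#'   direction, with a `status` column).
#' @param purpose `"reliability"` or `"validity"`.
#' @return list with `scores` (the filtered table), and `bookkeeping`:
#'   `planned`, named `excluded` counts, `available`, and
#'   `availability_pct` (rounded to the nearest integer percent).
#' @export
filter_available <- function(scores, purpose = c("reliability", "validity")) {
  purpose <- match.arg(purpose)
  dt <- as.data.table(scores)
  stopifnot(all(c("subject", "leg", "occasion", "direction", "status")
                %in% names(dt)))
  if (purpose == "validity") dt <- dt[direction == "down"]

  planned <- nrow(dt)
  if (planned == 0L) stop("no measures to filter", call. = FALSE)
  excl <- c(easy_mode = sum(dt$status == "easy_mode"),
            missing = sum(dt$status == "missing"),
            no_go = sum(dt$status == "no_go"))
  avail <- dt[status == "ok"]
  bookkeeping <- list(planned = planned, excluded = excl,
                      available = nrow(avail),
                      availability_pct = round(100 * nrow(avail) / planned))

  if (purpose == "reliability") {
    # keep only complete T1/T2 pairs per (subject, leg, direction)
    occ <- sort(unique(dt$occasion))[1:2]
    avail <- avail[occasion %in% occ]
    avail[, n_occ := .N, by = .(subject, leg, direction)]
    avail <- avail[n_occ == 2L][, n_occ := NULL]
  }
  list(scores = avail[], bookkeeping = bookkeeping)
}

#' @export
print.nta_result <- function(x, ...) {
  cat(sprintf("NTA (%s knee, way %s): %.2f deg, net shift %.2f cm over %.1f cm\n",
              x$leg, x$direction, x$nta, x$shift_cm, x$excursion_cm))
  invisible(x)
}
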