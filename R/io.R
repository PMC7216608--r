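# Tabular I/O: trajectory, ratings and score tables travel as plain CSV
# so any stage of the pipeline can be run from files.

#' Write a cohort's trajectories to CSV
#'
#' One long CSV holds every recording: metadata columns (`subject`, `leg`,
#' `occasion`, `status`) plus the samples (`time_s`, `knee_x_cm`,
#' `knee_y_cm`).
#'
#' @param cohort an `sls_cohort`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(cohort, path) {
  stopifnot(inherits(cohort, "sls_cohort"))
  dt <- cohort$recordings[cohort$trajectories,
                          on = c("subject", "leg", "occasion")]
  setcolorder(dt, c("subject", "leg", "occasion", "status",
                    "time_s", "knee_x_cm", "knee_y_cm"))
  fwrite(dt, path)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Parses and validates a trajectory CSV as written by
#' [write_trajectories()]: required columns present, strictly increasing
#' time within each recording, valid status values.  Malformed input is
#' rejected with the offending recording named.
#'
#' @param path CSV file path.
#' @return an `sls_cohort` (without a true-angle table).
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path)
  req <- c("subject", "leg", "occasion", "status",
           "time_s", "knee_x_cm", "knee_y_cm")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_status <- setdiff(unique(dt$status),
                        c("ok", "easy_mode", "missing", "no_go"))
  if (length(bad_status))
    stop("invalid status values: ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  bad <- dt[, .(bad = any(diff(time_s) <= 0)), by = .(subject, leg, occasion)]
  bad <- bad[bad == TRUE]
  if (nrow(bad))
    stop("non-increasing time in recording(s): ",
         paste(sprintf("%s/%s/%d", bad$subject, bad$leg, bad$occasion),
               collapse = "; "), call. = FALSE)
  recordings <- unique(dt[, .(subject, leg, occasion, status)])
  traj <- dt[, .(subject, leg, occasion, time_s, knee_x_cm, knee_y_cm)]
  structure(list(trajectories = traj, recordings = recordings,
                 true_angles = NULL, config = NULL),
            class = "sls_cohort")
}

#' Write/read a visual-ratings table
#'
#' Ratings CSV columns: `subject, leg, occasion, rater1, rater2,
#' consensus` (and `truth` when simulated).
#'
#' @param ratings an `sls_ratings` table.
#' @param path CSV file path.
#' @return the path (write) or the parsed table (read).
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(is.data.frame(ratings))
  fwrite(as.data.table(ratings), path)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path)
  req <- c("subject", "leg", "occasion", "consensus")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  setattr(dt, "class", c("sls_ratings", class(dt)))
  dt[]
}

#' Write/read a score table
#'
#' @param scores an `sls_scores` table.
#' @param path CSV file path.
#' @return the path (write) or the parsed table (read).
#' @export
write_scores <- function(scores, path) {
  stopifnot(is.data.frame(scores))
  fwrite(as.data.table(scores), path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path)
  req <- c("subject", "leg", "occasion", "direction", "status", "nta",
           "medial")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  setattr(dt, "class", c("sls_scores", class(dt)))
  dt[]
}
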