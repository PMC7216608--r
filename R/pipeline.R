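# End-to-end pipeline: simulate (optional) -> score -> filter ->
# reliability + validity -> rendered reports, with seed/config logging so
# identical configurations produce identical outputs.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] describing the simulation (used when
#'   no trajectory file is supplied).
#' @param trajectories_path,ratings_path optional input CSVs; when set,
#'   the pipeline skips simulation and reads these instead.
#' @param cutoffs strictly increasing positive cut-off grid for the
#'   validity sweep.
#' @param seed integer master seed; required for simulation runs.  Stage
#'   seeds are derived deterministically from it.
#' @param verbose emit progress messages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            trajectories_path = NULL,
                            ratings_path = NULL,
                            cutoffs = seq(2, 20, by = 2),
                            seed = 20170321L,
                            verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (length(cutoffs) < 1L || any(cutoffs <= 0) || any(diff(cutoffs) <= 0))
    stop("`cutoffs` must be strictly increasing and positive", call. = FALSE)
  if (is.null(trajectories_path) && is.null(seed))
    stop("a seed is required for simulation runs", call. = FALSE)
  structure(list(cohort = cohort, trajectories_path = trajectories_path,
                 ratings_path = ratings_path, cutoffs = cutoffs,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file; top-level fields mirror [pipeline_config()]
#'   arguments, with `cohort` a nested object of [cohort_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- do.call(cohort_config, as.list(js$cohort %||% list()))
  pipeline_config(
    cohort = cc,
    trajectories_path = js$trajectories_path %||% NULL,
    ratings_path = js$ratings_path %||% NULL,
    cutoffs = js$cutoffs %||% seq(2, 20, by = 2),
    seed = js$seed %||% 20170321L,
    verbose = js$verbose %||% FALSE
  )
}

#' Run the full screening-analysis pipeline
#'
#' Simulates (or reads) a cohort, contaminates it at the configured rates,
#' scores every recording, applies the availability filters, and computes
#' the test-retest reliability report and the construct-validity cut-off
#' sweep.  All randomness is routed through seeds derived from the master
#' seed, so a config run twice produces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, [render_reports()]
#'   writes CSV and Markdown reports there.
#' @return an `sls_pipeline_result` list: `cohort`, `scores`, `ratings`,
#'   `reliability`, `validity`, `bookkeeping` (reliability and validity
#'   availability), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  seed <- config$seed
  say("pipeline seed: %s", seed %||% "none")

  if (is.null(config$trajectories_path)) {
    cc <- config$cohort
    cc$seed <- seed
    say("simulating cohort: %d subjects x {%s} x %d occasions",
        cc$n_subjects, paste(cc$legs, collapse = ","), cc$occasions)
    cohort <- generate_cohort(cc)
    cohort <- contaminate(cohort, seed = seed + 1L)
  } else {
    say("reading trajectories from %s", config$trajectories_path)
    cohort <- read_trajectories(config$trajectories_path)
  }

  say("scoring %d recordings", nrow(cohort$recordings))
  scores <- score_cohort(cohort)

  rel_f <- filter_available(scores, "reliability")
  val_f <- filter_available(scores, "validity")
  say("reliability: %d/%d measures available (%d%%)",
      rel_f$bookkeeping$available, rel_f$bookkeeping$planned,
      rel_f$bookkeeping$availability_pct)
  say("validity: %d/%d recordings available (%d%%)",
      val_f$bookkeeping$available, val_f$bookkeeping$planned,
      val_f$bookkeeping$availability_pct)

  reliability <- reliability_report(scores)

  if (!is.null(config$ratings_path)) {
    ratings <- read_ratings(config$ratings_path)
  } else if (!is.null(cohort$true_angles)) {
    ratings <- generate_rater_labels(
      cohort$true_angles,
      label_threshold = config$cohort$label_threshold,
      rater_error_prob = config$cohort$rater_error_prob,
      seed = if (is.null(seed)) NULL else seed + 2L)
  } else {
    stop("validity stage needs a ratings file for non-simulated cohorts",
         call. = FALSE)
  }

  val_scores <- val_f$scores
  joined <- merge(val_scores[, .(subject, leg, occasion, medial)],
                  as.data.table(ratings)[, .(subject, leg, occasion,
                                             consensus)],
                  by = c("subject", "leg", "occasion"), sort = TRUE)
  validity <- cutoff_sweep(joined$medial, joined$consensus,
                           cutoffs = config$cutoffs)

  res <- structure(list(
    cohort = cohort, scores = scores, ratings = ratings,
    reliability = reliability, validity = validity,
    bookkeeping = list(reliability = rel_f$bookkeeping,
                       validity = val_f$bookkeeping),
    config = config
  ), class = "sls_pipeline_result")

  if (!is.null(out_dir)) render_reports(reliability, validity, out_dir)
  res
}

# internal: markdown table from a data.frame with 2-decimal display
.md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(round_half_up(x, 2), format = "f", digits = 2)
    else as.character(x)
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0L) return(c(header, sep))
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render reliability and validity reports to files
#'
#' Writes each report as a full-precision CSV plus a Markdown table with
#' two-decimal display (half-up rounding).  P-values below 0.05 are
#' starred in the Markdown rendering.  Bland-Altman point sets are written
#' one CSV per variable.
#'
#' @param reliability an `sls_reliability_report`.
#' @param validity an `sls_diagnostic_report`.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
render_reports <- function(reliability, validity, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  rel_csv <- file.path(out_dir, "reliability_report.csv")
  fwrite(as.data.table(as.data.frame(reliability)), rel_csv)
  files <- c(files, rel_csv)

  md <- as.data.frame(reliability)
  star <- function(p) ifelse(p < 0.05,
                             paste0(formatC(round_half_up(p, 3),
                                            format = "f", digits = 3), "*"),
                             formatC(round_half_up(p, 3), format = "f",
                                     digits = 3))
  disp <- data.frame(
    Variable = md$variable, n = md$n_pairs,
    `T1 median (Q1, Q3)` = sprintf("%.2f (%.2f, %.2f)",
                                   round_half_up(md$t1_median),
                                   round_half_up(md$t1_q1),
                                   round_half_up(md$t1_q3)),
    `T2 median (Q1, Q3)` = sprintf("%.2f (%.2f, %.2f)",
                                   round_half_up(md$t2_median),
                                   round_half_up(md$t2_q1),
                                   round_half_up(md$t2_q3)),
    `Grand median` = sprintf("%.2f", round_half_up(md$grand_median)),
    `T1 vs T2 p` = star(md$wilcoxon_p),
    `Spearman r (p)` = sprintf("%.2f (%s)", round_half_up(md$spearman_r),
                               star(md$spearman_p)),
    `ICC (95% CI)` = sprintf("%.2f (%.2f to %.2f)", round_half_up(md$icc),
                              round_half_up(md$icc_lo),
                              round_half_up(md$icc_hi)),
    SEM = sprintf("%.2f", round_half_up(md$sem)),
    SDC = sprintf("%.2f", round_half_up(md$sdc)),
    `Mean diff (95% CI)` = sprintf(
      "%.2f (%.2f to %.2f)%s", round_half_up(md$mean_diff),
      round_half_up(md$mean_diff_lo), round_half_up(md$mean_diff_hi),
      ifelse(md$systematic, " *", "")),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  rel_md <- file.path(out_dir, "reliability_report.md")
  writeLines(c("# Test-retest reliability", "", .md_table(disp)), rel_md)
  files <- c(files, rel_md)

  val_csv <- file.path(out_dir, "validity_report.csv")
  fwrite(as.data.table(as.data.frame(validity)), val_csv)
  files <- c(files, val_csv)

  vd <- as.data.frame(validity)
  vdisp <- data.frame(
    `Cut-off` = sprintf("%g deg", vd$cutoff),
    PA = sprintf("%.2f", round_half_up(vd$pa)),
    `Kappa (95% CI)` = sprintf("%.2f (%.2f to %.2f)",
                                round_half_up(vd$kappa),
                                round_half_up(vd$kappa_lo),
                                round_half_up(vd$kappa_hi)),
    `Se (95% CI)` = sprintf("%.2f (%.2f to %.2f)", round_half_up(vd$se),
                             round_half_up(vd$se_lo),
                             round_half_up(vd$se_hi)),
    `Sp (95% CI)` = sprintf("%.2f (%.2f to %.2f)", round_half_up(vd$sp),
                             round_half_up(vd$sp_lo),
                             round_half_up(vd$sp_hi)),
    `PPV (95% CI)` = sprintf("%.2f (%.2f to %.2f)", round_half_up(vd$ppv),
                              round_half_up(vd$ppv_lo),
                              round_half_up(vd$ppv_hi)),
    `NPV (95% CI)` = sprintf("%.2f (%.2f to %.2f)", round_half_up(vd$npv),
                              round_half_up(vd$npv_lo),
                              round_half_up(vd$npv_hi)),
    `AUC (SE, 95% CI)` = sprintf("%.2f (%.2f, %.2f to %.2f)",
                                  round_half_up(vd$auc),
                                  round_half_up(vd$auc_se),
                                  round_half_up(vd$auc_lo),
                                  round_half_up(vd$auc_hi)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  val_md <- file.path(out_dir, "validity_report.md")
  writeLines(c("# Construct validity", "",
               sprintf("Prevalence of reference fails: %d%%; best cut-off by AUC: %g deg",
                       attr(validity, "prevalence_pct"),
                       attr(validity, "best_cutoff")),
               "", .md_table(vdisp)), val_md)
  files <- c(files, val_md)

  ba <- attr(reliability, "bland_altman")
  for (v in names(ba)) {
    f <- file.path(out_dir,
                   sprintf("bland_altman_%s.csv", gsub(" ", "_", v)))
    fwrite(as.data.table(ba[[v]]$points), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' @export
print.sls_pipeline_result <- function(x, ...) {
  cat("SLS screening pipeline result\n")
  bk <- x$bookkeeping
  cat(sprintf("  reliability: %d/%d measures available (%d%%)\n",
              bk$reliability$available, bk$reliability$planned,
              bk$reliability$availability_pct))
  cat(sprintf("  validity: %d/%d recordings available (%d%%)\n",
              bk$validity$available, bk$validity$planned,
              bk$validity$availability_pct))
  print(x$reliability)
  print(x$validity)
  invisible(x)
}
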