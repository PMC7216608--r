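# Construct validity of the dichotomized screening score against
# consensus visual pass/fail ratings: 2x2 tables per cut-off, percent
# agreement and Cohen's kappa, sensitivity/specificity and predictive
# values with exact binomial intervals, and the two-segment binary-test
# ROC/AUC, swept over a grid of medial-displacement cut-offs.

#' Dichotomize medial displacement at a cut-off
#'
#' A measurement fails when the medial displacement is at or beyond the
#' cut-off (ties count as fail); lateral (negative) values always pass.
#'
#' @param medial numeric degrees of medial displacement (medial-positive).
#' @param cutoff positive cut-off in degrees.
#' @return character vector in `c("pass", "fail")`.
#' @examples
#' dichotomize(c(6, 5.9, -3), 6)  # fail, pass, pass
#' @export
dichotomize <- function(medial, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("`cutoff` must be a single positive number", call. = FALSE)
  ifelse(medial >= cutoff, "fail", "pass")
}

#' Consensus of two visual raters
#'
#' Equal labels win directly; disagreements are resolved by an
#' adjudicating third label (in simulation, a third rater drawn from the
#' truth model).  Without an adjudicator a disagreement is an error.
#'
#' @param r1,r2 character vectors in `c("pass", "fail")`.
#' @param adjudicator optional character vector used where `r1 != r2`.
#' @return character consensus labels.
#' @export
consensus_label <- function(r1, r2, adjudicator = NULL) {
  lv <- c("pass", "fail")
  if (!all(r1 %in% lv) || !all(r2 %in% lv))
    stop("labels must be 'pass' or 'fail'", call. = FALSE)
  if (length(r1) != length(r2))
    stop("rater label vectors must have equal length", call. = FALSE)
  disagree <- r1 != r2
  if (any(disagree) && is.null(adjudicator))
    stop("raters disagree and no adjudicator label is available",
         call. = FALSE)
  out <- r1
  if (any(disagree)) {
    adjudicator <- rep_len(adjudicator, length(r1))
    if (!all(adjudicator[disagree] %in% lv))
      stop("adjudicator labels must be 'pass' or 'fail'", call. = FALSE)
    out[disagree] <- adjudicator[disagree]
  }
  out
}

#' Cross-tabulate index-test labels against reference labels
#'
#' "fail" is the positive state: `tp` counts recordings failed by both the
#' index test and the reference.
#'
#' @param index,reference character vectors in `c("pass", "fail")` of equal
#'   length.
#' @return a `contingency_2x2` list: `tp`, `fp`, `fn`, `tn`, `n`,
#'   `prevalence` (reference-positive proportion) and `prevalence_pct`
#'   (rounded percent).
#' @examples
#' contingency(c("fail", "pass"), c("fail", "fail"))
#' @export
contingency <- function(index, reference) {
  if (length(index) != length(reference))
    stop("index and reference labels must have equal length", call. = FALSE)
  lv <- c("pass", "fail")
  if (!all(index %in% lv) || !all(reference %in% lv))
    stop("labels must be 'pass' or 'fail'", call. = FALSE)
  n <- length(index)
  if (n < 1L) stop("empty label sets", call. = FALSE)
  tp <- sum(index == "fail" & reference == "fail")
  fp <- sum(index == "fail" & reference == "pass")
  fn <- sum(index == "pass" & reference == "fail")
  tn <- sum(index == "pass" & reference == "pass")
  prev <- (tp + fn) / n
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 prevalence = prev, prevalence_pct = round(100 * prev)),
            class = "contingency_2x2")
}

#' Percent agreement and Cohen's kappa with 95% CI
#'
#' `PA = (tp + tn) / n`; kappa is `(P0 - Pe) / (1 - Pe)` with the expected
#' agreement `Pe` computed from the table margins.  The confidence
#' interval is `kappa +/- 1.96 * SE` with the standard large-sample
#' (Fleiss-Cohen-Everitt) standard error, clipped to `[-1, 1]`.
#'
#' @param t a `contingency_2x2`.
#' @param conf_level confidence level (default 0.95).
#' @return list: `pa`, `pe`, `kappa`, `kappa_ci`, `se`, `degenerate`
#'   (TRUE when `Pe = 1` makes kappa undefined).
#' @examples
#' tab <- structure(list(tp = 40, fp = 20, fn = 10, tn = 30, n = 100),
#'                  class = "contingency_2x2")
#' agreement_stats(tab)$kappa  # 0.40
#' @export
agreement_stats <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  n <- t$n
  p <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2, 2) / n  # rows = index, cols = ref
  # p[i, j]: i indexes the index-test state (1 = fail), j the reference
  pr <- rowSums(p)
  pc <- colSums(p)
  p0 <- p[1, 1] + p[2, 2]
  pe <- pr[1] * pc[1] + pr[2] * pc[2]
  if (abs(1 - pe) < 1e-12) {
    return(list(pa = p0, pe = pe, kappa = NA_real_,
                kappa_ci = c(NA_real_, NA_real_), se = NA_real_,
                degenerate = TRUE))
  }
  kappa <- (p0 - pe) / (1 - pe)
  # large-sample SE of kappa (Fleiss, Cohen & Everitt 1969)
  diag_term <- sum(diag(p) * (1 - (pr + pc) * (1 - kappa))^2)
  off <- (1 - kappa)^2 * (p[1, 2] * (pc[1] + pr[2])^2 +
                            p[2, 1] * (pc[2] + pr[1])^2)
  c_term <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, diag_term + off - c_term)) / ((1 - pe) * sqrt(n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(-1, kappa - z * se), min(1, kappa + z * se))
  list(pa = p0, pe = unname(pe), kappa = unname(kappa), kappa_ci = unname(ci),
       se = unname(se), degenerate = FALSE)
}

# internal: exact (Clopper-Pearson) binomial CI
.clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

#' Sensitivity, specificity, and predictive values with exact CIs
#'
#' `Se = tp / (tp + fn)`, `Sp = tn / (tn + fp)`, `PPV = tp / (tp + fp)`,
#' `NPV = tn / (tn + fn)`; all intervals are exact binomial
#' (Clopper-Pearson).  A statistic with a zero denominator is reported as
#' `NA` with its `undefined` flag set.
#'
#' @param t a `contingency_2x2`.
#' @param conf_level confidence level (default 0.95).
#' @return list with elements `se`, `sp`, `ppv`, `npv`, each a list
#'   `(est, ci, undefined)`.
#' @export
diagnostic_stats <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  one <- function(x, n) {
    if (n == 0)
      return(list(est = NA_real_, ci = c(NA_real_, NA_real_),
                  undefined = TRUE))
    list(est = x / n, ci = .clopper_pearson(x, n, conf_level),
         undefined = FALSE)
  }
  list(se = one(t$tp, t$tp + t$fn),
       sp = one(t$tn, t$tn + t$fp),
       ppv = one(t$tp, t$tp + t$fp),
       npv = one(t$tn, t$tn + t$fn))
}

#' AUC of a dichotomized (binary) test
#'
#' The ROC of a single-cut-off test is the two-segment curve through
#' `(0, 0)`, `(1 - Sp, Se)`, `(1, 1)`; its area is `(Se + Sp) / 2`.  When
#' the positive/negative counts are supplied the Hanley-McNeil standard
#' error and a Wald 95% CI (clipped to `[0, 1]`) are reported.
#'
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @param n_pos,n_neg optional counts of reference-positive and
#'   reference-negative recordings.
#' @param conf_level confidence level (default 0.95).
#' @return list: `auc`, `se_auc`, `ci`, `label` (accuracy band).
#' @examples
#' binary_auc(0.86, 0.78)$auc  # 0.82
#' @export
binary_auc <- function(se, sp, n_pos = NULL, n_neg = NULL,
                       conf_level = 0.95) {
  .check_prob(se, "se")
  .check_prob(sp, "sp")
  auc <- (se + sp) / 2
  se_auc <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.null(n_pos) && !is.null(n_neg) && n_pos > 0 && n_neg > 0) {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se_auc <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- c(max(0, auc - z * se_auc), min(1, auc + z * se_auc))
  }
  list(auc = auc, se_auc = se_auc, ci = ci, label = auc_label(auc))
}

#' Diagnostic-accuracy sweep over medial-displacement cut-offs
#'
#' For every cut-off the way-down medial displacements are dichotomized
#' and cross-tabulated against the reference labels; percent agreement,
#' kappa, Se/Sp/PPV/NPV (exact binomial CIs) and the binary-test AUC
#' (Hanley-McNeil SE) are reported per cut-off.  The flagged best cut-off
#' maximises the AUC (first on ties).
#'
#' @param medial numeric way-down medial displacements, degrees.
#' @param reference character consensus labels aligned with `medial`.
#' @param cutoffs strictly increasing positive cut-off grid (degrees),
#'   default 2 to 20 in steps of 2.
#' @param conf_level confidence level (default 0.95).
#' @return an `sls_diagnostic_report` data.frame (one row per cut-off)
#'   with attributes `prevalence`, `prevalence_pct`, `best_cutoff`, `n`.
#' @export
cutoff_sweep <- function(medial, reference, cutoffs = seq(2, 20, by = 2),
                         conf_level = 0.95) {
  if (length(medial) == 0L) stop("empty data", call. = FALSE)
  if (length(medial) != length(reference))
    stop("scores and labels must be aligned", call. = FALSE)
  if (length(cutoffs) < 1L || any(cutoffs <= 0) ||
      any(diff(cutoffs) <= 0))
    stop("`cutoffs` must be strictly increasing and positive", call. = FALSE)
  keep <- is.finite(medial)
  medial <- medial[keep]
  reference <- reference[keep]
  if (length(medial) == 0L) stop("no finite scores", call. = FALSE)

  n_pos <- sum(reference == "fail")
  n_neg <- sum(reference == "pass")
  rows <- lapply(cutoffs, function(co) {
    idx <- dichotomize(medial, co)
    tab <- contingency(idx, reference)
    ag <- agreement_stats(tab, conf_level)
    ds <- diagnostic_stats(tab, conf_level)
    auc <- binary_auc(ds$se$est, ds$sp$est, n_pos, n_neg, conf_level)
    data.frame(
      cutoff = co, pa = ag$pa,
      kappa = ag$kappa, kappa_lo = ag$kappa_ci[1L], kappa_hi = ag$kappa_ci[2L],
      se = ds$se$est, se_lo = ds$se$ci[1L], se_hi = ds$se$ci[2L],
      sp = ds$sp$est, sp_lo = ds$sp$ci[1L], sp_hi = ds$sp$ci[2L],
      ppv = ds$ppv$est, ppv_lo = ds$ppv$ci[1L], ppv_hi = ds$ppv$ci[2L],
      npv = ds$npv$est, npv_lo = ds$npv$ci[1L], npv_hi = ds$npv$ci[2L],
      auc = auc$auc, auc_se = auc$se_auc,
      auc_lo = auc$ci[1L], auc_hi = auc$ci[2L],
      auc_label = auc$label,
      index_positive_prop = mean(idx == "fail"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "prevalence") <- n_pos / length(reference)
  attr(out, "prevalence_pct") <- round(100 * n_pos / length(reference))
  attr(out, "best_cutoff") <- cutoffs[which.max(out$auc)]
  attr(out, "n") <- length(medial)
  class(out) <- c("sls_diagnostic_report", "data.frame")
  out
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table (n=%d): tp=%d fp=%d fn=%d tn=%d; prevalence %d%%\n",
              x$n, x$tp, x$fp, x$fn, x$tn, x$prevalence_pct))
  invisible(x)
}

#' @export
print.sls_diagnostic_report <- function(x, ...) {
  cat(sprintf(
    "Construct-validity sweep (n=%d, prevalence %d%%, best cut-off %g deg)\n",
    attr(x, "n"), attr(x, "prevalence_pct"), attr(x, "best_cutoff")))
  df <- as.data.frame(x)[, c("cutoff", "pa", "kappa", "se", "sp",
                             "ppv", "npv", "auc")]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
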