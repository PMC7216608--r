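# Test-retest reliability statistics for paired (T1, T2) measurements:
# nonparametric descriptives, Wilcoxon signed-rank, Spearman correlation,
# a two-way variance decomposition feeding the agreement ICC, SEM and the
# smallest detectable change, the t-based mean-difference CI, and
# Bland-Altman limits of agreement.

#' Nonparametric descriptives of a paired series
#'
#' Medians and quartiles per occasion plus the grand median/quartiles over
#' the pooled T1 and T2 measurements.  Quartiles use linear interpolation
#' (quantile type 7).
#'
#' @param t1,t2 numeric vectors of equal length (or a two-column object as
#'   `t1`).
#' @return list with `t1`, `t2`, `grand`, each `c(median, q1, q3)`.
#' @export
descriptives <- function(t1, t2 = NULL) {
  p <- .as_pairs(t1, t2)
  if (length(p$t1) < 1L) stop("empty series", call. = FALSE)
  qs <- function(x) {
    q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    c(median = q[1L], q1 = q[2L], q3 = q[3L])
  }
  list(t1 = qs(p$t1), t2 = qs(p$t2), grand = qs(c(p$t1, p$t2)))
}

# internal: exact null distribution of the signed-rank statistic by
# polynomial (subset-sum) convolution over doubled midranks.  Returns the
# two-sided p for observed statistic v (sum of positive-difference ranks).
.wilcoxon_exact_p <- function(ranks, v) {
  w <- as.integer(round(2 * ranks))  # midranks doubled -> integers
  total <- sum(w)
  counts <- rep(0, total + 1L)
  counts[1L] <- 1
  for (wi in w) {
    shifted <- c(rep(0, wi), counts[seq_len(total + 1L - wi)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(w)
  support <- 0:total            # support of 2 * V
  mu <- total / 2
  dev <- abs(2 * v - mu)
  # sign-flip null is symmetric about mu, so two-sided = tail mass at
  # least as extreme on either side
  sum(probs[abs(support - mu) >= dev - 1e-9])
}

#' Wilcoxon signed-rank test for a systematic T1/T2 difference
#'
#' Zero differences are dropped (Wilcoxon's original rule) and ties get
#' midranks.  The null distribution is enumerated exactly for up to 25
#' non-zero differences; above that a normal approximation with continuity
#' correction and tie-corrected variance is used.  The p-value is
#' two-sided.
#'
#' @param t1,t2 numeric vectors of equal length (or a two-column object).
#' @return list: `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_used` (non-zero differences), `method`, `significant`
#'   (at p < 0.05).
#' @export
wilcoxon_signed_rank <- function(t1, t2 = NULL) {
  p <- .as_pairs(t1, t2)
  d <- p$t2 - p$t1
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; degenerate data", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate", significant = FALSE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    pv <- .wilcoxon_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu - 0.5 * sign(v - mu)) / sigma
    pv <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  pv <- min(1, pv)
  list(statistic = v, p_value = pv, n_used = n, method = method,
       significant = pv < 0.05)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks for ties; the two-sided p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param t1,t2 numeric vectors of equal length (or a two-column object),
#'   n >= 3.
#' @return list: `r`, `p_value`, `n`, `label` (magnitude band).
#' @export
spearman_rho <- function(t1, t2 = NULL) {
  p <- .as_pairs(t1, t2)
  n <- length(p$t1)
  if (n < 3L) stop("Spearman correlation needs n >= 3", call. = FALSE)
  if (var(p$t1) == 0 || var(p$t2) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  r <- cor(rank(p$t1), rank(p$t2))
  if (abs(r) >= 1 - 1e-12) {
    pv <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    pv <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = pv, n = n, label = spearman_label(r))
}

#' Two-way variance decomposition of a paired series
#'
#' ANOVA mean squares of the subjects-by-occasions layout (one observation
#' per cell, k = 2 occasions) converted to variance components:
#' `sigma2_res = MSE`, `sigma2_o = max(0, (MSC - MSE) / n)`,
#' `sigma2_p = max(0, (MSR - MSE) / k)`.  Negative estimates are truncated
#' at zero, standard ANOVA practice.
#'
#' @param t1,t2 numeric vectors of equal length n >= 2 (complete pairs; do
#'   pairwise deletion upstream).
#' @return a `variance_components` list: `sigma2_p`, `sigma2_o`,
#'   `sigma2_res`, `n`, `k`, and the untruncated mean squares `msr`,
#'   `msc`, `mse` used for ICC confidence limits.
#' @examples
#' variance_components(c(1, 3, 5), c(2, 4, 6))  # sigma2_p 4, sigma2_o 0.5
#' @export
variance_components <- function(t1, t2 = NULL) {
  p <- .as_pairs(t1, t2)
  n <- length(p$t1)
  if (n < 2L) stop("variance decomposition needs n >= 2 pairs", call. = FALSE)
  k <- 2L
  x <- cbind(p$t1, p$t2)
  g <- mean(x)
  subj <- rowMeans(x)
  occ <- colMeans(x)
  ssr <- k * sum((subj - g)^2)
  ssc <- n * sum((occ - g)^2)
  sst <- sum((x - g)^2)
  sse <- max(0, sst - ssr - ssc)   # guard float negatives
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  structure(list(
    sigma2_p = max(0, (msr - mse) / k),
    sigma2_o = max(0, (msc - mse) / n),
    sigma2_res = mse,
    n = n, k = k, msr = msr, msc = msc, mse = mse
  ), class = "variance_components")
}

#' Build a variance_components object from known components
#'
#' Useful for evaluating the ICC/SEM formulas at stated component values
#' (e.g. simulation targets) without raw data.
#'
#' @param sigma2_p,sigma2_o,sigma2_res non-negative variance components
#'   (deg^2).
#' @param n,k optional design sizes; needed for ICC confidence limits.
#' @return a `variance_components` object.
#' @export
make_variance_components <- function(sigma2_p, sigma2_o, sigma2_res,
                                     n = NULL, k = 2L) {
  .check_nonneg(sigma2_p, "sigma2_p")
  .check_nonneg(sigma2_o, "sigma2_o")
  .check_nonneg(sigma2_res, "sigma2_res")
  msr <- k * sigma2_p + sigma2_res
  msc <- if (is.null(n)) NA_real_ else n * sigma2_o + sigma2_res
  structure(list(sigma2_p = sigma2_p, sigma2_o = sigma2_o,
                 sigma2_res = sigma2_res, n = n, k = k,
                 msr = msr, msc = msc, mse = sigma2_res),
            class = "variance_components")
}

#' Agreement ICC from variance components
#'
#' Single-measure intraclass correlation of absolute agreement,
#' `ICC = sigma2_p / (sigma2_p + sigma2_o + sigma2_res)`, with a 95%
#' confidence interval from the F-based absolute-agreement single-measure
#' interval (McGraw & Wong) when the design sizes are known.
#'
#' @param vc a `variance_components` object.
#' @param conf_level confidence level (default 0.95).
#' @return list: `icc`, `ci` (length 2, `NA` when `n` unknown), `label`
#'   (relative-reliability band).
#' @examples
#' icc_agreement(make_variance_components(75, 5, 20))$icc  # 0.75
#' @export
icc_agreement <- function(vc, conf_level = 0.95) {
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$sigma2_p + vc$sigma2_o + vc$sigma2_res
  if (denom == 0)
    stop("all variance components are zero: ICC undefined", call. = FALSE)
  icc <- vc$sigma2_p / denom
  ci <- c(NA_real_, NA_real_)
  if (!is.null(vc$n) && is.finite(vc$msc %||% NA_real_) && vc$n >= 2) {
    n <- vc$n; k <- vc$k
    msr <- vc$msr; msc <- vc$msc; mse <- vc$mse
    alpha <- 1 - conf_level
    if (1 - icc < 1e-12) {
      ci <- c(1, 1)
    } else {
      # McGraw & Wong, absolute agreement, single measure
      r <- icc
      a <- (k * r) / (n * (1 - r))
      b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- qf(1 - alpha / 2, n - 1, v)
      fu <- qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(max(-1, lower), min(1, upper))
    }
  }
  list(icc = icc, ci = ci, label = icc_label(icc))
}

#' Standard error of measurement (agreement form)
#'
#' `SEM = sqrt(sigma2_o + sigma2_res)`: absolute reliability on the scale
#' of the measurement, including any occasion effect.
#'
#' @param vc a `variance_components` object.
#' @return SEM in the measurement's units (degrees here).
#' @export
sem_agreement <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  sqrt(vc$sigma2_o + vc$sigma2_res)
}

#' Smallest detectable change
#'
#' `SDC = 1.96 * sqrt(2) * SEM`: the change beyond measurement error at
#' the 95% level for a difference between two measurements.  Returned at
#' full precision; rendered reports round to two decimals.
#'
#' @param sem standard error of measurement (>= 0), or a
#'   `variance_components` object.
#' @return SDC in the measurement's units.
#' @examples
#' smallest_detectable_change(10.66)  # 29.5498...
#' @export
smallest_detectable_change <- function(sem) {
  if (inherits(sem, "variance_components")) sem <- sem_agreement(sem)
  .check_nonneg(sem, "sem")
  1.96 * sqrt(2) * sem
}

#' Mean T2 - T1 difference with t-based confidence interval
#'
#' A 95% CI excluding zero flags a systematic change between occasions.
#'
#' @param t1,t2 numeric vectors of equal length n >= 2 (or a two-column
#'   object).
#' @param conf_level confidence level (default 0.95).
#' @return list: `mean_diff`, `ci`, `systematic` (TRUE iff the CI excludes
#'   zero).
#' @export
mean_difference_ci <- function(t1, t2 = NULL, conf_level = 0.95) {
  p <- .as_pairs(t1, t2)
  d <- p$t2 - p$t1
  n <- length(d)
  if (n < 2L) stop("mean-difference CI needs n >= 2", call. = FALSE)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    ci <- c(m, m)
  } else {
    half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  }
  list(mean_diff = m, ci = ci,
       systematic = ci[1L] > 0 || ci[2L] < 0)
}

#' Bland-Altman analysis of a paired series
#'
#' Points are (pair mean, T2 - T1 difference); the bias is the mean
#' difference and the limits of agreement are `bias +/- 1.96 * SD` of the
#' differences.  The proportional-bias slope is the OLS slope of the
#' differences on the pair means (`NA` when the means are constant).
#'
#' @param t1,t2 numeric vectors of equal length n >= 2.
#' @return list: `points` (data.frame `mean`, `diff`), `bias`, `loa`
#'   (length 2), `prop_bias_slope`.
#' @export
bland_altman <- function(t1, t2 = NULL) {
  p <- .as_pairs(t1, t2)
  if (length(p$t1) < 2L) stop("Bland-Altman needs n >= 2", call. = FALSE)
  m <- (p$t1 + p$t2) / 2
  d <- p$t2 - p$t1
  bias <- mean(d)
  s <- sd(d)
  slope <- if (var(m) == 0) NA_real_ else cov(d, m) / var(m)
  list(points = data.frame(mean = m, diff = d),
       bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       prop_bias_slope = slope)
}

#' Full test-retest reliability report over a score table
#'
#' For every variable (leg x phase direction) with complete T1/T2 pairs:
#' medians and quartiles per occasion, grand median, Wilcoxon signed-rank
#' p, Spearman correlation, agreement ICC with 95% CI, SEM, SDC, and the
#' mean T2 - T1 difference with 95% CI.  Statistics are computed on the
#' signed NTA values (the reporting convention used in screening tables).
#'
#' @param scores a filtered `sls_scores` table (see [filter_available()]
#'   with purpose `"reliability"`), or an unfiltered one (filtering is
#'   applied).
#' @return an `sls_reliability_report` data.frame, one row per variable,
#'   with a `bland_altman` attribute (named list of point sets) and a
#'   `bookkeeping` attribute.
#' @export
reliability_report <- function(scores) {
  if (!is.data.frame(scores)) stop("`scores` must be a score table", call. = FALSE)
  fa <- filter_available(scores, "reliability")
  dt <- fa$scores
  if (nrow(dt) == 0L) stop("no complete pairs available", call. = FALSE)
  occ <- sort(unique(dt$occasion))
  wide <- dcast(dt, subject + leg + direction ~ occasion,
                value.var = "nta")
  setnames(wide, as.character(occ), c("t1", "t2"))

  ba_sets <- list()
  rows <- list()
  for (lg in sort(unique(wide$leg))) {
    for (dir in c("up", "down")) {
      w <- wide[leg == lg & direction == dir]
      if (nrow(w) < 3L) next
      varname <- sprintf("%s knee %s", lg, dir)
      des <- descriptives(w$t1, w$t2)
      wil <- wilcoxon_signed_rank(w$t1, w$t2)
      sp <- spearman_rho(w$t1, w$t2)
      vc <- variance_components(w$t1, w$t2)
      icc <- icc_agreement(vc)
      sem <- sem_agreement(vc)
      sdc <- smallest_detectable_change(sem)
      md <- mean_difference_ci(w$t1, w$t2)
      ba_sets[[varname]] <- bland_altman(w$t1, w$t2)
      rows[[varname]] <- data.frame(
        variable = varname, n_pairs = nrow(w),
        t1_median = des$t1[["median"]], t1_q1 = des$t1[["q1"]],
        t1_q3 = des$t1[["q3"]],
        t2_median = des$t2[["median"]], t2_q1 = des$t2[["q1"]],
        t2_q3 = des$t2[["q3"]],
        grand_median = des$grand[["median"]],
        grand_q1 = des$grand[["q1"]], grand_q3 = des$grand[["q3"]],
        wilcoxon_p = wil$p_value,
        spearman_r = sp$r, spearman_p = sp$p_value,
        icc = icc$icc, icc_lo = icc$ci[1L], icc_hi = icc$ci[2L],
        icc_label = icc$label,
        sem = sem, sdc = sdc,
        mean_diff = md$mean_diff, mean_diff_lo = md$ci[1L],
        mean_diff_hi = md$ci[2L], systematic = md$systematic,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L)
    stop("no variable has enough complete pairs (need >= 3)", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bland_altman") <- ba_sets
  attr(out, "bookkeeping") <- fa$bookkeeping
  class(out) <- c("sls_reliability_report", "data.frame")
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components (n=%s, k=%d): sigma2_p=%.4g, sigma2_o=%.4g, sigma2_res=%.4g\n",
    x$n %||% "?", x$k, x$sigma2_p, x$sigma2_o, x$sigma2_res))
  invisible(x)
}

#' @export
print.sls_reliability_report <- function(x, ...) {
  cat("Test-retest reliability report\n")
  df <- as.data.frame(x)
  show <- df[, c("variable", "n_pairs", "grand_median", "wilcoxon_p",
                 "spearman_r", "icc", "sem", "sdc")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], round_half_up, 2)
  print(show, row.names = FALSE)
  invisible(x)
}
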