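#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero
#' (so 0.125 -> 0.13 at two decimals), matching how clinical reliability
#' tables are usually typeset. Base R's `round()` rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the display precision
#'   used throughout the package's rendered reports).
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(29.5498, -2.145, 0.005))
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# qualitative band labels -----------------------------------------------

# relative-reliability bands for the ICC
icc_label <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc < 0) "poor"
  else if (icc <= 0.20) "slight"
  else if (icc <= 0.40) "fair"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "substantial"
  else "almost perfect"
}

# Spearman correlation magnitude bands; the conventional scale leaves
# [0.5, 0.6) unnamed, we fold it into "fair" (see the methods vignette)
spearman_label <- function(r) {
  a <- abs(r)
  if (a < 0.3) "low"
  else if (a < 0.6) "fair"
  else if (a < 0.8) "moderately strong"
  else "very strong"
}

# discriminative-accuracy bands for a binary-test AUC
auc_label <- function(auc) {
  if (auc > 0.9) "high accuracy"
  else if (auc >= 0.7) "moderate accuracy"
  else if (auc > 0.5) "low accuracy"
  else if (auc == 0.5) "a chance result"
  else "below chance"
}

# internal: check a probability-like scalar
.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative number", name),
         call. = FALSE)
  invisible(x)
}

# internal: coerce the various paired-series inputs (two vectors, a
# two-column matrix/data.frame, or a list with t1/t2) to a clean pair list
.as_pairs <- function(t1, t2 = NULL) {
  if (is.null(t2)) {
    if (is.matrix(t1)) {
      stopifnot(ncol(t1) >= 2L)
      t2 <- as.numeric(t1[, 2L])
      t1 <- as.numeric(t1[, 1L])
    } else if (is.data.frame(t1)) {
      stopifnot(ncol(t1) >= 2L)
      t2 <- as.numeric(t1[[2L]])
      t1 <- as.numeric(t1[[1L]])
    } else if (is.list(t1) && all(c("t1", "t2") %in% names(t1))) {
      t2 <- as.numeric(t1$t2)
      t1 <- as.numeric(t1$t1)
    } else {
      stop("supply `t1` and `t2`, or a two-column object", call. = FALSE)
    }
  }
  t1 <- as.numeric(t1)
  t2 <- as.numeric(t2)
  if (length(t1) != length(t2))
    stop("t1 and t2 must have equal length", call. = FALSE)
  if (anyNA(t1) || anyNA(t2))
    stop("paired series must be complete; drop incomplete pairs upstream",
         call. = FALSE)
  list(t1 = t1, t2 = t2)
}

`%||%` <- function(a, b) tryCatch(if (is.null(a)) b else a, error = function(e) b)
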