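# Shared fixtures, built in code.

# paired series used to pin ICC/kappa values against independent
# implementations (frozen oracle values computed once from
# pingouin.intraclass_corr / statsmodels cohens_kappa on these numbers)
fix_t1 <- c(7.636, 10.106, 3.934, 4.549, 14.714, 6.263, 15.294, 12.5,
            9.817, 5.984, 6.686, 8.607, 3.847, 8.978, 5.4)
fix_t2 <- c(8.167, 10.049, 6.653, 3.569, 13.575, 5.057, 15.754, 11.893,
            11.198, 6.667, 7.204, 8.638, 2.433, 8.925, 3.441)

# a small clean cohort most tests can share
small_cohort <- function(n = 6, seed = 42, noise = 0, ...) {
  generate_cohort(cohort_config(n_subjects = n, sensor_noise_sd = noise,
                                seed = seed, ...))
}

# brute-force two-sided signed-rank p by enumerating all 2^n sign vectors
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# hand-rolled type-7 quantile (sort and interpolate) used as the
# descriptives oracle
sort_index_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# build a contingency_2x2 from counts via labelled vectors (exercises the
# public constructor instead of poking the structure)
counts_table <- function(tp, fp, fn, tn) {
  idx <- rep(c("fail", "fail", "pass", "pass"), c(tp, fp, fn, tn))
  ref <- rep(c("fail", "pass", "fail", "pass"), c(tp, fp, fn, tn))
  contingency(idx, ref)
}
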