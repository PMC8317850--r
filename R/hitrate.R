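#' Per-patient hit rate
#'
#' The hit rate is the fraction of shockwaves that hit the stone; at a
#' constant pulse rate it equals the fraction of frames in which the stone
#' is in focus.
#'
#' @param n_focus Frames annotated in focus.
#' @param n_total Total annotated frames (> 0).
#' @return Fraction `n_focus / n_total`.
#' @export
hit_rate <- function(n_focus, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_focus < 0) || any(n_focus > n_total))
    stop("n_focus must be in [0, n_total]")
  n_focus / n_total
}

# Jackknife leave-one-out statistics (vectorised for the mean).
.jackknife <- function(x, statistic) {
  n <- length(x)
  if (identical(statistic, "mean")) {
    (sum(x) - x) / (n - 1)
  } else {
    f <- if (is.character(statistic)) get(statistic) else statistic
    vapply(seq_len(n), function(i) f(x[-i]), numeric(1))
  }
}

.stat_fun <- function(statistic) {
  if (is.character(statistic)) {
    switch(statistic, mean = mean, median = stats::median,
           stop("unknown statistic"))
  } else statistic
}

# Bootstrap distribution of a statistic under iid resampling.
.boot_dist <- function(x, statistic, n_samples) {
  n <- length(x)
  draws <- matrix(sample(x, n * n_samples, replace = TRUE), n, n_samples)
  if (identical(statistic, "mean")) colMeans(draws)
  else apply(draws, 2L, .stat_fun(statistic))
}

#' Bias-corrected and accelerated (BCa) bootstrap
#'
#' Resamples the data with replacement, computes the statistic on each
#' resample, and forms a 95% (by default) BCa confidence interval: the
#' bias correction `z0` comes from the fraction of bootstrap statistics
#' below the observed value and the acceleration `a` from the skewness of
#' the jackknife leave-one-out statistics. The reported point estimate is
#' the median of the bootstrap distribution (for a per-patient hit rate
#' this is the "median hit rate"); the plug-in statistic of the original
#' data is returned alongside.
#'
#' @param x Numeric data vector (frame labels 0/1 for a per-patient rate,
#'   or per-patient rates for a cohort summary).
#' @param statistic `"mean"`, `"median"`, or a function of a numeric
#'   vector. The resampling unit is always an element of `x`.
#' @param n_samples Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `bootstrap_result`: `point_estimate` (median
#'   of the bootstrap distribution), `plug_in`, `ci_low`, `ci_high`,
#'   `n_samples`, `seed`, `t` (the bootstrap statistics, for convergence
#'   tracing).
#' @export
bca_bootstrap <- function(x, statistic = "mean", n_samples = 5000L,
                          seed = 1L, conf = 0.95) {
  if (length(x) == 0L) stop("x must be nonempty")
  if (n_samples < 100L) stop("n_samples must be >= 100")
  f <- .stat_fun(statistic)
  t0 <- f(x)
  t <- withr::with_seed(as.integer(seed), .boot_dist(x, statistic, n_samples))
  if (stats::var(x) == 0 || stats::var(t) == 0) {
    # constant data: the interval collapses to the observed value
    return(structure(list(point_estimate = t0, plug_in = t0,
                          ci_low = t0, ci_high = t0,
                          n_samples = as.integer(n_samples),
                          seed = as.integer(seed), conf = conf, t = t),
                     class = "bootstrap_result"))
  }
  z0 <- stats::qnorm((sum(t < t0) + 0.5 * sum(t == t0)) / n_samples)
  jack <- .jackknife(x, statistic)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  zal <- stats::qnorm(c((1 - conf) / 2, (1 + conf) / 2))
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  ci <- stats::quantile(t, adj, names = FALSE, type = 6)
  structure(list(point_estimate = stats::median(t), plug_in = t0,
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 conf = conf, t = t),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.1f%% (%.0f%% CI %.1f-%.1f%%), %d BCa bootstrap resamples\n",
              100 * x$point_estimate, 100 * x$conf, 100 * x$ci_low,
              100 * x$ci_high, x$n_samples))
  invisible(x)
}

#' Per-patient median hit rate with BCa confidence interval
#'
#' Resamples individual frame labels (0/1) of one patient and bootstraps
#' the frame-level mean; the reported value is the median of that bootstrap
#' distribution with its BCa interval.
#'
#' @param labels Integer 0/1 frame labels for one patient.
#' @param n_samples Resamples (default 5000 at frame level).
#' @param seed Integer seed.
#' @return A `bootstrap_result`.
#' @export
patient_hit_rate_ci <- function(labels, n_samples = 5000L, seed = 1L) {
  bca_bootstrap(as.numeric(labels), "mean", n_samples, seed)
}

#' Cohort hit rate with BCa confidence interval
#'
#' Summarises the per-patient (median) hit rates at the patient level:
#' resamples the vector of per-patient rates and bootstraps its mean. The
#' patient level is the appropriate unit when the pooling test
#' ([pooling_chi2()]) rejects homogeneity of the per-patient rates.
#'
#' @param rates Per-patient hit rates (fractions).
#' @param n_samples Resamples (default 3000 at patient level, the point
#'   where the convergence trace of the 95th percentile stabilises below
#'   1%).
#' @param seed Integer seed.
#' @param statistic Cohort summary statistic; the default `"mean"` averages
#'   the per-patient median hit rates.
#' @return A `bootstrap_result`.
#' @export
cohort_hit_rate_ci <- function(rates, n_samples = 3000L, seed = 1L,
                               statistic = "mean") {
  bca_bootstrap(as.numeric(rates), statistic, n_samples, seed)
}

#' Convergence trace of a bootstrap percentile
#'
#' Tracks a percentile of the bootstrap distribution as the number of
#' resamples grows and reports the relative change between consecutive
#' grid points, the diagnostic used to pick a sufficient number of
#' resamples: once consecutive changes stay below 1%, adding resamples no
#' longer moves the tail of the distribution.
#'
#' @param x Data vector.
#' @param statistic As in [bca_bootstrap()].
#' @param percentile Tracked percentile of the bootstrap distribution in
#'   `(0, 1)` (default 0.95).
#' @param n_grid Increasing vector of resample counts.
#' @param seed Integer seed.
#' @return A data.frame with columns `n` (grid point) and `rel_change`
#'   (relative change of the tracked percentile against the previous grid
#'   point; length `length(n_grid) - 1`).
#' @export
convergence_trace <- function(x, statistic = "mean", percentile = 0.95,
                              n_grid = seq(500L, 5000L, by = 500L),
                              seed = 1L) {
  if (is.unsorted(n_grid, strictly = TRUE)) stop("n_grid must be increasing")
  t <- withr::with_seed(as.integer(seed),
                        .boot_dist(x, statistic, max(n_grid)))
  q <- vapply(n_grid, function(n) stats::quantile(t[seq_len(n)], percentile,
                                                  names = FALSE), numeric(1))
  d <- diff(q)
  prev <- q[-length(q)]
  rel <- ifelse(d == 0, 0, abs(d) / abs(prev))
  data.frame(n = n_grid[-1L], rel_change = rel)
}

#' Small-sample normality diagnostics of the hit-rate distribution
#'
#' Computes the adjusted Fisher-Pearson skewness and excess kurtosis (the
#' convention SPSS prints) standardised by their small-sample standard
#' errors, plus a Shapiro-Wilk test. `|z| < 1.96` and `p > 0.05` are the
#' usual no-evidence-against-normality readings.
#'
#' @param rates Per-patient hit rates (n >= 3).
#' @return A list: `skewness`, `kurtosis`, `skew_z`, `kurt_z`, `shapiro_p`.
#' @export
normality_diagnostics <- function(rates) {
  n <- length(rates)
  if (n < 3L) stop("need at least 3 rates")
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  skw <- e1071::skewness(rates, type = 2L)
  if (n >= 4L) {
    se_kurt <- sqrt(4 * (n^2 - 1) * se_skew^2 / ((n - 3) * (n + 5)))
    krt <- e1071::kurtosis(rates, type = 2L)
    kz <- krt / se_kurt
  } else {
    krt <- NA_real_; kz <- NA_real_
  }
  list(skewness = skw, kurtosis = krt,
       skew_z = skw / se_skew, kurt_z = kz,
       shapiro_p = stats::shapiro.test(rates)$p.value)
}

#' Chi-square pooling test for hit-rate homogeneity
#'
#' Decides whether frames from all patients may be pooled into one
#' population: under the null hypothesis every patient shares the pooled
#' hit rate, so the expected number of hits for patient *i* is
#' `n_total_i * pooled_rate`. The statistic sums `(O - E)^2 / E` over the
#' per-patient hit counts with `k - 1` degrees of freedom. A significant
#' result (p < alpha) rejects homogeneity, and the cohort summary must
#' then be computed at the patient level rather than the frame level.
#'
#' Note the statistic is built from the hit-count cells alone (not hit and
#' miss cells); this is the construction whose value matches a manual
#' goodness-of-fit computation on the per-patient table with `df = k - 1`.
#'
#' @param patients A data.frame with columns `n_focus` and `n_total`, one
#'   row per patient (>= 2 rows).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `pooling_decision`: `chi2`, `df`, `p_value`,
#'   `pooled` (TRUE when pooling is appropriate), `pooled_rate`,
#'   `contributions` (per-patient terms).
#' @export
pooling_chi2 <- function(patients, alpha = 0.05) {
  if (!all(c("n_focus", "n_total") %in% names(patients)))
    stop("patients needs columns n_focus and n_total")
  if (nrow(patients) < 2L) stop("need at least 2 patients")
  if (any(patients$n_total <= 0)) stop("every patient needs n_total > 0")
  pooled_rate <- sum(patients$n_focus) / sum(patients$n_total)
  expected <- patients$n_total * pooled_rate
  contrib <- (patients$n_focus - expected)^2 / expected
  chi2 <- sum(contrib)
  df <- nrow(patients) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p_value = p, pooled = p >= alpha,
                 pooled_rate = pooled_rate, alpha = alpha,
                 contributions = contrib),
            class = "pooling_decision")
}

#' @export
print.pooling_decision <- function(x, ...) {
  cat(sprintf("Pooled hit rate %.2f%%; chi-square %.1f on %d df, p %s\n",
              100 * x$pooled_rate, x$chi2, x$df,
              format.pval(x$p_value, digits = 3)))
  cat(if (x$pooled) "Hit rates homogeneous: pooling frames is appropriate\n"
      else "Hit rates heterogeneous: summarise at the patient level\n")
  invisible(x)
}
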