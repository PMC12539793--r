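#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval `p_hat +- z * sqrt(p_hat (1 - p_hat) / n)`,
#' reported in percent and clipped to `[0, 100]`.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (`n >= 1`).
#' @param conf Confidence level.
#' @return List with `k`, `n`, `p_hat` (proportion), `pct`, `lower`, `upper`
#'   (percent scale), `conf`.
#' @export
wald_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop_fv("n must be >= 1")
  if (k < 0 || k > n) stop_fv("k must be in [0, n]")
  p <- k / n
  z <- qnorm((1 + conf) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  list(k = k, n = n, p_hat = p, pct = 100 * p,
       lower = max(0, 100 * (p - half)), upper = min(100, 100 * (p + half)),
       conf = conf)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' removed; absolute differences are ranked with midranks for ties;
#' `W = min(sum of positive ranks, sum of negative ranks)`. For `m <= 20`
#' nonzero differences the p value is exact over all `2^m` equally likely
#' sign assignments (computed by a generating-function recursion over the
#' doubled midranks, which enumerates the same distribution); for larger `m`
#' a normal approximation with tie correction is used. The two-sided p is
#' `P(W+ <= W) + P(W+ >= total - W)`, capped at 1.
#'
#' @param diffs Numeric vector of paired differences with at least one
#'   nonzero value.
#' @return List with `W`, `p`, `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  m <- length(d)
  if (!m) stop_fv("all differences are zero; signed-rank test not computable")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  total <- m * (m + 1) / 2
  if (m <= 20) {
    # distribution of 2*W+ over sign assignments via polynomial convolution
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(length(counts) - rk)])
      counts <- counts + shifted
    }
    probs <- counts / 2^m
    sums <- seq_along(counts) - 1  # in units of 2*rank
    p <- sum(probs[sums <= 2 * W + 1e-9]) +
      sum(probs[sums >= 2 * (total - W) - 1e-9])
    method <- "exact"
  } else {
    mu <- total / 2
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(W = W, p = min(1, p), n_nonzero = m, method = method)
}

#' Paired two-tailed t test on differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`.
#'
#' @param diffs Numeric vector of paired differences, `n >= 2`, nonzero
#'   variance.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
paired_t <- function(diffs) {
  n <- length(diffs)
  if (n < 2) stop_fv("need at least two differences")
  s <- sd(diffs)
  if (s == 0) stop_fv("degenerate variance")
  t_stat <- mean(diffs) / (s / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), df = n - 1))
}

#' Cohen's dz effect size for paired differences
#'
#' `dz = mean(d) / sd(d)` (sample sd, `n - 1` denominator); satisfies
#' `dz * sqrt(n) = t` wherever both are defined.
#'
#' @inheritParams paired_t
#' @return Numeric effect size.
#' @export
cohens_dz <- function(diffs) {
  n <- length(diffs)
  if (n < 2) stop_fv("need at least two differences")
  s <- sd(diffs)
  if (s == 0) stop_fv("degenerate variance")
  mean(diffs) / s
}

#' Median and interquartile range
#'
#' Quartiles by the linear-interpolation convention
#' (`stats::quantile(type = 7)`).
#'
#' @param values Nonempty numeric vector.
#' @return List with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (!length(values)) stop_fv("empty input")
  q <- quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[[2]], q1 = q[[1]], q3 = q[[3]])
}

#' Seeded percentile bootstrap confidence interval
#'
#' Resamples the data with replacement `B` times, evaluates `statistic` on
#' each resample and returns the percentile interval. Resamples on which the
#' statistic is undefined (returns `NA`/`NaN` or errors) are redrawn, with a
#' cap on redraws.
#'
#' @param statistic Function of a resample (vector or data frame of rows).
#' @param sample Numeric vector or data frame to resample.
#' @param B Number of bootstrap replicates (`>= 100`).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf Confidence level.
#' @return List with `lower`, `upper`, `B`, `redraws`.
#' @export
bootstrap_ci <- function(statistic, sample, B = 2000, seed = 1, conf = 0.95) {
  if (B < 100) stop_fv("B must be >= 100")
  n <- if (is.data.frame(sample)) nrow(sample) else length(sample)
  take <- function(idx) {
    if (is.data.frame(sample)) sample[idx, , drop = FALSE] else sample[idx]
  }
  with_seed(seed, {
    stats_out <- numeric(B)
    redraws <- 0L
    max_redraws <- 10L * B
    for (b in seq_len(B)) {
      repeat {
        val <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          stop_fv("statistic undefined on too many bootstrap resamples")
        }
      }
      stats_out[[b]] <- val
    }
    q <- quantile(stats_out, probs = c((1 - conf) / 2, (1 + conf) / 2),
                  names = FALSE, type = 7)
    list(lower = q[[1]], upper = q[[2]], B = B, redraws = redraws)
  })
}
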