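#' Aggregate entries into a monthly series
#'
#' Counts posts and comments per UTC calendar month. The month grid is
#' contiguous over the study window (or the observed range when no window is
#' given): months with no entries are present with zero counts, so totals
#' conserve corpus size.
#'
#' @param entries Entries data frame.
#' @param window Optional length-2 bound (POSIXct or UNIX seconds); the grid
#'   spans the months containing `window[1]` up to (excluding) `window[2]`.
#' @return A `monthly_series` data frame: `year`, `month`, `posts`,
#'   `comments`.
#' @export
monthly_counts <- function(entries, window = NULL) {
  t <- utc_time(entries$created_utc)
  ym <- as.integer(format(t, "%Y")) * 12L + as.integer(format(t, "%m")) - 1L
  if (!is.null(window)) {
    wt <- utc_time(as.numeric(window))
    lo <- as.integer(format(wt[1], "%Y")) * 12L + as.integer(format(wt[1], "%m")) - 1L
    # window end is exclusive: the month containing (end - 1 second) is last
    hi_t <- utc_time(as.numeric(window[2]) - 1)
    hi <- as.integer(format(hi_t, "%Y")) * 12L + as.integer(format(hi_t, "%m")) - 1L
  } else if (length(ym)) {
    lo <- min(ym); hi <- max(ym)
  } else {
    stop_fv("no entries and no window: month grid undefined")
  }
  grid <- lo:hi
  posts <- tabulate(match(ym[entries$kind == "post"], grid), length(grid))
  comments <- tabulate(match(ym[entries$kind == "comment"], grid), length(grid))
  out <- data.frame(year = grid %/% 12L, month = grid %% 12L + 1L,
                    posts = posts, comments = comments)
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Trailing moving average
#'
#' Trailing mean over the last `min(window, t)` observations: the head of
#' the series uses an expanding window, so the output has the same length as
#' the input.
#'
#' @param values Numeric vector.
#' @param window Window length (`>= 1`).
#' @return Numeric vector of smoothed values.
#' @export
moving_average <- function(values, window = 12) {
  if (window < 1) stop_fv("window must be >= 1")
  n <- length(values)
  if (!n) return(numeric())
  cs <- cumsum(values)
  idx <- seq_len(n)
  full <- idx >= window
  out <- numeric(n)
  out[!full] <- cs[!full] / idx[!full]
  if (any(full)) {
    out[full] <- (cs[full] - c(0, cs)[idx[full] - window + 1]) / window
  }
  out
}

segment_cost_table <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  function(i, j) {
    # SSE of x[i..j] around its mean
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    s2 - s^2 / (j - i + 1)
  }
}

#' Penalized change-point detection (piecewise-constant mean)
#'
#' Exact dynamic-programming minimization of segmented squared error plus a
#' per-change-point penalty, for a piecewise-constant mean model.
#' Deterministic. The default penalty is `2 * log(T) * vhat` with `vhat` a
#' robust noise-variance estimate `(mad(diff(x)) / sqrt(2))^2` (falling back
#' to `var(x)` when the MAD is zero), so that the level shifts being sought
#' do not inflate the penalty through the variance estimate.
#'
#' For count series whose noise variance grows with the level (monthly
#' posting volumes are Poisson-like), `variance_stabilize = TRUE` runs the
#' segmentation on the square-root scale `2 * sqrt(x)`, where Poisson noise
#' has approximately unit variance regardless of level; breakpoints then
#' reflect relative rather than absolute shifts, and reported segment means
#' remain on the original scale.
#'
#' @param values Numeric series (length `>= 2 * min_size`).
#' @param penalty Positive penalty per change point; `NULL` for the default.
#' @param min_size Minimum segment length.
#' @param series_name Label carried into the result.
#' @param variance_stabilize Segment `2 * sqrt(x)` instead of `x`
#'   (nonnegative series only).
#' @return A `change_points` object: list with `series_name`, `breakpoints`
#'   (1-based indices of the first point of each new segment, strictly
#'   increasing), `penalty`, `segment_means`, `cost`.
#' @export
detect_change_points <- function(values, penalty = NULL, min_size = 2,
                                 series_name = "series",
                                 variance_stabilize = FALSE) {
  n <- length(values)
  if (n < 2 * min_size) stop_fv("series too short for min_size = %d", min_size)
  raw <- values
  if (variance_stabilize) {
    if (any(values < 0)) stop_fv("variance stabilization needs a nonnegative series")
    values <- 2 * sqrt(values)
  }
  if (is.null(penalty)) {
    if (variance_stabilize) {
      # on the 2*sqrt scale Poisson noise has unit variance by construction
      penalty <- 2 * log(n)
    } else {
      vhat <- if (n >= 3) (mad(diff(values)) / sqrt(2))^2 else var(values)
      if (!is.finite(vhat) || vhat == 0) vhat <- var(values)
      if (!is.finite(vhat) || vhat == 0) vhat <- 1e-8
      penalty <- 2 * log(n) * vhat
    }
  }
  if (penalty <= 0) stop_fv("penalty must be positive")
  cost <- segment_cost_table(values)
  # F[j+1]: optimal penalized cost of x[1..j]; F[1] = -penalty
  F <- rep(Inf, n + 1)
  F[1] <- -penalty
  prev <- integer(n + 1)
  for (j in seq_len(n)) {
    cand_t <- 0:(j - min_size)
    cand_t <- cand_t[cand_t == 0 | cand_t >= min_size]
    if (!length(cand_t)) next
    vals <- vapply(cand_t, function(t) F[t + 1] + cost(t + 1, j) + penalty,
                   numeric(1))
    best <- which.min(vals)
    F[j + 1] <- vals[best]
    prev[j + 1] <- cand_t[best]
  }
  # recover segmentation
  bps <- integer()
  j <- n
  while (j > 0) {
    t <- prev[j + 1]
    if (t > 0) bps <- c(t + 1L, bps)
    j <- t
  }
  starts <- c(1L, bps)
  ends <- c(bps - 1L, n)
  means <- vapply(seq_along(starts),
                  function(k) mean(raw[starts[k]:ends[k]]), numeric(1))
  structure(list(series_name = series_name, breakpoints = bps,
                 penalty = penalty, segment_means = means,
                 cost = F[n + 1]),
            class = "change_points")
}

#' @export
print.change_points <- function(x, ...) {
  cat(sprintf("<change_points> %s: %s (penalty %.3g)\n", x$series_name,
              if (length(x$breakpoints)) paste(x$breakpoints, collapse = ", ")
              else "none", x$penalty))
  invisible(x)
}

#' Seasonal activity profile
#'
#' Mean posts and comments per calendar month, averaging across the years of
#' the series.
#'
#' @param series A `monthly_series` from [monthly_counts()] with at least 12
#'   months.
#' @return Data frame `month` (1-12), `posts_mean`, `comments_mean`.
#' @export
seasonal_profile <- function(series) {
  if (nrow(series) < 12) stop_fv("need at least 12 months of data")
  out <- data.frame(
    month = 1:12,
    posts_mean = vapply(1:12, function(m) mean(series$posts[series$month == m]),
                        numeric(1)),
    comments_mean = vapply(1:12, function(m) mean(series$comments[series$month == m]),
                           numeric(1)))
  out
}

#' Paired post-vs-comment comparison over the seasonal profile
#'
#' Differences are mean comments minus mean posts per calendar month
#' (12 pairs). Reports how many months comments exceed posts, the median
#' difference with IQR, the exact Wilcoxon signed-rank test, the paired t
#' test and Cohen's dz. When all differences are zero the signed-rank test
#' is reported as not computable rather than erroring.
#'
#' @param profile Seasonal profile from [seasonal_profile()].
#' @return A `paired_comparison` list: `n_pairs`, `months_exceeding`,
#'   `median_diff`, `iqr`, `W`, `p_wilcoxon`, `t`, `df`, `p_t`, `dz`,
#'   and `note` when a statistic was not computable.
#' @export
post_comment_comparison <- function(profile) {
  diffs <- profile$comments_mean - profile$posts_mean
  mi <- median_iqr(diffs)
  out <- list(n_pairs = length(diffs),
              months_exceeding = sum(diffs > 0),
              median_diff = mi$median, iqr = c(mi$q1, mi$q3))
  wil <- tryCatch(wilcoxon_signed_rank(diffs), error = function(e) NULL)
  if (is.null(wil)) {
    out$W <- NA_real_; out$p_wilcoxon <- NA_real_
    out$note <- "signed-rank test not computable (all differences zero)"
  } else {
    out$W <- wil$W; out$p_wilcoxon <- wil$p
  }
  tt <- tryCatch(paired_t(diffs), error = function(e) NULL)
  if (is.null(tt)) {
    out$t <- NA_real_; out$df <- length(diffs) - 1; out$p_t <- NA_real_
    out$dz <- NA_real_
    out$note <- c(out$note, "t test not computable (degenerate variance)")
  } else {
    out$t <- tt$t; out$df <- tt$df; out$p_t <- tt$p
    out$dz <- cohens_dz(diffs)
  }
  structure(out, class = "paired_comparison")
}

#' Map change-point indices to calendar months
#'
#' @param result A `change_points` object computed on a monthly series.
#' @param series The `monthly_series` the detection ran on.
#' @return Character vector `YYYY-MM`, one per breakpoint.
#' @export
breakpoint_months <- function(result, series) {
  sprintf("%04d-%02d", series$year[result$breakpoints],
          series$month[result$breakpoints])
}
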