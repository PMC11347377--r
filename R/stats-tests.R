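#' Paired samples t-test
#'
#' Two-sided paired t-test on the per-subject differences
#' \code{after - before}. Incomplete pairs are dropped. When the differences
#' have zero variance the test statistic is undefined and the result is
#' flagged degenerate (with \code{t = 0, p = 1} in the trivial all-equal
#' case).
#'
#' @param before,after paired numeric vectors of equal length (n >= 2 after
#'   removing incomplete pairs).
#' @return List with \code{t}, \code{p}, \code{mean_diff}, \code{df},
#'   \code{n}, \code{degenerate}.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after))
    stop_arg("before and after must have equal length")
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  n <- length(before)
  if (n < 2L) stop_arg("need at least 2 complete pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    zero <- mean(d) == 0
    return(structure(list(t = if (zero) 0 else NA_real_,
                          p = if (zero) 1 else NA_real_,
                          mean_diff = mean(d), df = n - 1L, n = n,
                          degenerate = TRUE), class = "paired_t"))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 mean_diff = unname(tt$estimate), df = unname(tt$parameter),
                 n = n, degenerate = FALSE), class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: mean diff %.4g, t = %.3f, df = %d, p = %.3g%s\n",
              x$mean_diff, x$t, x$df, x$p,
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}

#' Independent samples t-test
#'
#' Two-sided two-sample t-test; the classic equal-variance form by default
#' (set \code{var_equal = FALSE} for Welch).
#'
#' @param group_a,group_b numeric vectors, each with at least 2 finite
#'   values.
#' @param var_equal assume equal variances (default \code{TRUE}).
#' @return List with \code{t}, \code{p}, \code{mean_a}, \code{mean_b},
#'   \code{df}, \code{degenerate}.
#' @export
independent_t <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_arg("each group needs at least 2 finite values")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    zero <- mean(group_a) == mean(group_b)
    return(structure(list(t = if (zero) 0 else NA_real_,
                          p = if (zero) 1 else NA_real_,
                          mean_a = mean(group_a), mean_b = mean(group_b),
                          df = NA_real_, degenerate = TRUE),
                     class = "independent_t"))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 df = unname(tt$parameter), degenerate = FALSE),
            class = "independent_t")
}

#' @export
print.independent_t <- function(x, ...) {
  cat(sprintf("Independent t-test: means %.4g vs %.4g, t = %.3f, p = %.3g\n",
              x$mean_a, x$mean_b, x$t, x$p))
  invisible(x)
}

#' Effect-size magnitude label
#'
#' Standardized-mean-difference magnitudes: |d| > 0.2 small, > 0.5 medium,
#' > 0.8 large (strict inequalities, so d = 0.5 is still "small").
#'
#' @param d finite standardized mean difference (vectorized).
#' @return Character: \code{"none"}, \code{"small"}, \code{"medium"} or
#'   \code{"large"}.
#' @export
magnitude_label <- function(d) {
  if (any(!is.finite(d))) stop_arg("d must be finite")
  c("none", "small", "medium", "large")[
    1L + (abs(d) > 0.2) + (abs(d) > 0.5) + (abs(d) > 0.8)]
}

#' Standardized mean difference (Cohen's d) for paired measurements
#'
#' \code{d = (mean(after) - mean(before)) / s_pooled} with
#' \code{s_pooled = sqrt((sd_before^2 + sd_after^2) / 2)}. Because the two
#' measurements come from the same subjects, the 95\% confidence interval
#' uses a paired-design standard error
#' \code{SE = sqrt(2 (1 - r) / n + d^2 / (2 n))}, where \code{r} is the
#' before/after correlation; a correlated design yields much narrower
#' intervals than independent groups would.
#'
#' @param before,after paired numeric vectors, n >= 3 complete pairs.
#' @return An \code{smd_result}: \code{d}, \code{ci_low}, \code{ci_high},
#'   \code{se}, \code{r}, \code{n}, \code{magnitude}, \code{degenerate}.
#' @export
smd <- function(before, after) {
  if (length(before) != length(after))
    stop_arg("before and after must have equal length")
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  n <- length(before)
  if (n < 3L) stop_arg("need at least 3 complete pairs")
  s_pooled <- sqrt((stats::var(before) + stats::var(after)) / 2)
  if (s_pooled == 0) {
    zero <- mean(after) == mean(before)
    d <- if (zero) 0 else NA_real_
    return(structure(list(d = d, ci_low = d, ci_high = d, se = NA_real_,
                          r = NA_real_, n = n,
                          magnitude = if (zero) "none" else NA_character_,
                          degenerate = TRUE), class = "smd_result"))
  }
  d <- (mean(after) - mean(before)) / s_pooled
  r <- if (stats::sd(before) > 0 && stats::sd(after) > 0)
    stats::cor(before, after) else 0
  se <- sqrt(2 * (1 - r) / n + d^2 / (2 * n))
  z <- stats::qnorm(0.975)
  structure(list(d = d, ci_low = d - z * se, ci_high = d + z * se, se = se,
                 r = r, n = n, magnitude = magnitude_label(d),
                 degenerate = FALSE), class = "smd_result")
}

#' Standardized mean difference from summary statistics
#'
#' Pooled-SD Cohen's d computed from reported means and SDs alone (no
#' confidence interval, since the before/after correlation is unknown).
#' Useful for checking published tables against rounded summary rows.
#'
#' @param mean_before,mean_after,sd_before,sd_after summary statistics.
#' @return Cohen's d.
#' @export
smd_from_summary <- function(mean_before, mean_after, sd_before, sd_after) {
  s_pooled <- sqrt((sd_before^2 + sd_after^2) / 2)
  if (any(s_pooled == 0)) stop_arg("pooled SD is zero")
  (mean_after - mean_before) / s_pooled
}

#' @export
print.smd_result <- function(x, ...) {
  cat(sprintf("SMD (Cohen's d): %.3f [%.3f, %.3f], n = %d, %s effect\n",
              x$d, x$ci_low, x$ci_high, x$n, x$magnitude))
  invisible(x)
}

#' Correlation between two variables
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value.
#' Constant input yields a degenerate result (\code{r = NA}) rather than an
#' error, so screens over many columns can proceed.
#'
#' @param x,y numeric vectors; pairwise-complete observations are used
#'   (n >= 3).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return A \code{correlation_result}: \code{r}, \code{p}, \code{n},
#'   \code{method}, \code{degenerate}.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_arg("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n = n, method = method,
                          degenerate = TRUE), class = "correlation_result"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 method = method, degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.3g, n = %d\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}
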