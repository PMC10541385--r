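#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected rank correlation (Pearson correlation of the ranks) with a
#' two-sided p-value from the t-distribution approximation
#' `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite.
#' @return A list with `r` and `p`.
#' @examples
#' spearman_cor(1:10, (1:10)^2)  # r = 1
#' @export
spearman_cor <- function(x, y) {
  check_paired(x, y, 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p)
}

#' Bland-Altman agreement statistics
#'
#' Mean paired difference and 95% limits of agreement
#' `mean(a-b) +/- 1.96 sd(a-b)` (sample SD, n-1 denominator).
#'
#' @param a,b Equal-length numeric vectors (the two methods' measurements).
#' @return A list with `mean_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b) {
  check_paired(a, b, 2)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped. The exact null distribution is used for up
#' to 25 non-zero untied differences; otherwise the tie-corrected normal
#' approximation with continuity correction. Two-sided p-value.
#'
#' @param a,b Equal-length numeric vectors.
#' @return A list with `statistic` (V, the positive-rank sum) and `p`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  check_paired(a, b, 2)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero; test degenerate", call. = FALSE)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

check_paired <- function(a, b, nmin) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(a) < nmin)
    stop(sprintf("need at least %d pairs", nmin), call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("values must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Combined agreement report for two volume series
#'
#' Convenience wrapper producing the three validation statistics used to
#' compare lesion volumes between pipelines or against clinical scores.
#'
#' @param a,b Equal-length numeric vectors.
#' @return A list with `spearman_r`, `spearman_p`, `ba_mean_diff`,
#'   `ba_loa_low`, `ba_loa_high`, `wilcoxon_stat`, `wilcoxon_p`.
#' @export
stats_report <- function(a, b) {
  sp <- spearman_cor(a, b)
  ba <- bland_altman(a, b)
  wx <- tryCatch(wilcoxon_signed_rank(a, b),
                 error = function(e) list(statistic = NA_real_, p = NA_real_))
  list(spearman_r = sp$r, spearman_p = sp$p,
       ba_mean_diff = ba$mean_diff, ba_loa_low = ba$loa_low,
       ba_loa_high = ba$loa_high,
       wilcoxon_stat = wx$statistic, wilcoxon_p = wx$p)
}
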