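#' Wilcoxon matched-pairs signed-rank test (normal approximation)
#'
#' Paired comparison of available against ideal supply across facilities.
#' Zero differences are dropped (Wilcoxon's original procedure); absolute
#' differences are ranked with mid-ranks for ties; the statistic `W` is the
#' smaller of the positive and negative rank sums; the two-sided p-value
#' comes from the normal approximation
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` with no continuity
#' correction.  When fewer than `min_pairs` nonzero differences remain, the
#' test is skipped (p-value `NA`) rather than errored, mirroring strata in
#' which the comparison is not computable.
#'
#' @param available,ideal Paired numeric vectors (one entry per facility).
#' @param min_pairs Minimum usable pairs (default 2).
#' @return A list of class `hrgap_test`: `method`, `n` (usable pairs),
#'   `statistic` (`W`), `p_value`, `skipped`, `reason`.
#' @examples
#' wilcoxon_signed_rank(rep(0, 12), 1:12)$p_value # ~0.0022, all one-signed
#' @export
wilcoxon_signed_rank <- function(available, ideal, min_pairs = 2L) {
  stopifnot(length(available) == length(ideal))
  d <- available - ideal
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < min_pairs) {
    return(new_test_result("wilcoxon_signed_rank", n, NA_real_, NA_real_,
                           skipped = TRUE,
                           reason = if (n == 0L) "all differences zero"
                                    else "fewer than 2 nonzero differences"))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (w - mu) / sigma
  p <- min(1, 2 * pnorm(-abs(z)))
  new_test_result("wilcoxon_signed_rank", n, w, p)
}

#' Friedman rank test for k matched samples
#'
#' Compares available supply and the two ideal-supply channels as three
#' matched columns across facilities.  Ranks are assigned within each row
#' (mid-ranks for ties); the statistic is
#' `chi2_F = 12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)` on `k - 1` degrees
#' of freedom.
#'
#' @param columns Numeric matrix or data frame, one row per facility, one
#'   column per matched sample (k >= 2; the pipeline uses k = 3).
#' @param min_rows Minimum rows required (default 2); fewer rows skip the
#'   test.
#' @return A list of class `hrgap_test` (see [wilcoxon_signed_rank()]).
#' @export
friedman_rank_test <- function(columns, min_rows = 2L) {
  m <- as.matrix(columns)
  if (!is.numeric(m)) stop("friedman_rank_test: columns must be numeric")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2L) stop("friedman_rank_test: need at least 2 matched columns")
  if (n < min_rows) {
    return(new_test_result("friedman", n, NA_real_, NA_real_, skipped = TRUE,
                           reason = "fewer than 2 complete rows"))
  }
  ranks <- t(apply(m, 1L, rank))
  rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  new_test_result("friedman", n, stat, p)
}

new_test_result <- function(method, n, statistic, p_value,
                            skipped = FALSE, reason = NA_character_) {
  structure(list(method = method, n = n, statistic = statistic,
                 p_value = p_value, skipped = skipped, reason = reason),
            class = "hrgap_test")
}

#' @export
print.hrgap_test <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("%s: skipped (%s), n = %d\n", x$method, x$reason, x$n))
  } else {
    cat(sprintf("%s: statistic = %.4g, n = %d, two-sided p = %.4g\n",
                x$method, x$statistic, x$n, x$p_value))
  }
  invisible(x)
}

#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' Percent-scale interval `p +/- z * sqrt(p (1 - p) / total)`, clipped to
#' [0, 100].
#'
#' @param count Number of successes (0 <= count <= total).
#' @param total Number of trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return List of class `hrgap_prop_ci`: `count`, `total`, `point`,
#'   `lower`, `upper`, `level`, all percentages on the 0-100 scale.
#' @examples
#' proportion_ci(489, 866) # point 56.5, CI about 53 to 60 percent
#' @export
proportion_ci <- function(count, total, level = 0.95) {
  stopifnot(length(count) == 1L, length(total) == 1L)
  if (!is.finite(total) || total <= 0)
    stop("proportion_ci: 'total' must be positive")
  if (!is.finite(count) || count < 0 || count > total)
    stop("proportion_ci: 'count' must satisfy 0 <= count <= total")
  if (level <= 0 || level >= 1)
    stop("proportion_ci: 'level' must be in (0, 1)")
  p <- count / total
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / total)
  structure(list(count = count, total = total,
                 point = 100 * p,
                 lower = max(0, 100 * (p - z * se)),
                 upper = min(100, 100 * (p + z * se)),
                 level = level),
            class = "hrgap_prop_ci")
}

#' @export
print.hrgap_prop_ci <- function(x, ...) {
  cat(sprintf("%d / %d = %.1f%% (%.0f%% CI %.0f-%.0f)\n",
              x$count, x$total, x$point, 100 * x$level,
              round_half_up(x$lower, 0), round_half_up(x$upper, 0)))
  invisible(x)
}
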