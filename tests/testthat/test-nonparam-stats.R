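test_that("signed-rank test reproduces the one-signed n = 12 p-value", {
  # every facility short by a different amount: W = 0
  res <- wilcoxon_signed_rank(rep(0, 12), 1:12)
  expect_equal(res$statistic, 0)
  expect_equal(res$n, 12)
  expect_equal(res$p_value, 0.00221772146424, tolerance = 1e-9)
  # one pair reversed with the smallest rank: W = 1
  res1 <- wilcoxon_signed_rank(c(0.5, rep(0, 11)), c(0.1, 1:11))
  expect_equal(res1$statistic, 1)
  expect_equal(res1$p_value, 0.00287341392785, tolerance = 1e-9)
})

test_that("signed-rank test skips when no information remains", {
  same <- wilcoxon_signed_rank(c(3, 4, 5), c(3, 4, 5))
  expect_true(same$skipped)
  expect_true(is.na(same$p_value))
  expect_match(same$reason, "zero")
  one <- wilcoxon_signed_rank(c(3, 4, 5), c(3, 4, 9))
  expect_true(one$skipped)
})

test_that("normal approximation tracks the exact sign-flip oracle (n >= 9)", {
  # exhaustive enumeration shows the uncorrected approximation stays within
  # 0.02 of the exact mid-p for every statistic only from n = 9 on (below
  # that, deviations up to 0.037 occur for mid-range statistics, i.e. large
  # p-values); random paired draws over the everywhere-valid range
  set.seed(31)
  for (i in 1:20) {
    n <- sample(9:12, 1)
    a <- rnorm(n, 10, 4)
    b <- rnorm(n, 11, 4)
    res <- wilcoxon_signed_rank(a, b)
    expect_lt(abs(res$p_value - exact_wilcoxon_p(a, b)), 0.02)
  }
  # in the rejection tails the agreement holds from n = 5 already
  for (n in 5:6) {
    a <- rnorm(n, 10, 1)
    b <- a + runif(n, 1, 2)   # one-signed differences, W = 0
    expect_lt(abs(wilcoxon_signed_rank(a, b)$p_value - exact_wilcoxon_p(a, b)),
              0.02)
  }
})

test_that("signed-rank p is invariant under reordering and global sign flip", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    p0 <- wilcoxon_signed_rank(a, b)$p_value
    o <- sample(n)
    expect_equal(wilcoxon_signed_rank(a[o], b[o])$p_value, p0)
    expect_equal(wilcoxon_signed_rank(b, a)$p_value, p0)
  }
})

test_that("Friedman statistic hits its closed forms", {
  # identical columns: no discrimination
  m <- matrix(rep(c(4, 7, 1, 9), 3), ncol = 3)
  res <- friedman_rank_test(m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # strict common ordering across 12 rows: rank sums 12/24/36, statistic 2n
  m <- cbind(1:12, 13:24, 25:36)
  res <- friedman_rank_test(m)
  expect_equal(res$statistic, 24)
  expect_equal(res$n, 12)
  expect_lt(res$p_value, 1e-5)
  expect_true(friedman_rank_test(m[1, , drop = FALSE])$skipped)
})

test_that("Friedman statistic is rank-based and bounded by 2n for k = 3", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    m <- matrix(rexp(n * 3), ncol = 3)
    s0 <- friedman_rank_test(m)$statistic
    expect_lte(s0, 2 * n + 1e-9)
    # monotone transformation of whole rows leaves within-row ranks alone
    mt <- t(apply(m, 1, function(r) exp(r) + runif(1)))
    expect_equal(friedman_rank_test(mt)$statistic, s0)
  }
})

test_that("Friedman chi-square p tracks the permutation null where it is used", {
  # the chi-square approximation is only trustworthy in the rejection region:
  # exact enumeration of the n = 6, k = 3 null shows deviations up to 0.13
  # for mid-range statistics but < 0.05 once the statistic reaches 3 (p
  # around 0.25 and below), which is where the supply comparisons live
  m5 <- rbind(matrix(rep(c(1, 2, 3), each = 5) + runif(15, 0, 0.2), ncol = 3),
              c(3, 2, 1))          # five concordant rows, one inverted
  res <- friedman_rank_test(m5)
  expect_gte(res$statistic, 3)
  expect_lt(abs(res$p_value - friedman_perm_p(m5)), 0.05)
  strict <- cbind(1:6, 7:12, 13:18) # perfect ordering, statistic 2n
  expect_lt(abs(friedman_rank_test(strict)$p_value - friedman_perm_p(strict)),
            0.05)
})

test_that("proportion intervals reproduce the printed workforce CIs", {
  ci <- proportion_ci(489, 866)
  expect_equal(round_half_up(ci$lower, 0), 53)
  expect_equal(round_half_up(ci$upper, 0), 60)
  ci <- proportion_ci(250, 1000)
  expect_equal(ci$lower, 22.3162087844, tolerance = 1e-8)
  expect_equal(ci$upper, 27.6837912156, tolerance = 1e-8)
  expect_equal(proportion_ci(0, 100)$lower, 0)
  expect_equal(proportion_ci(100, 100)$upper, 100)
  expect_error(proportion_ci(5, 0), "positive")
  expect_error(proportion_ci(7, 5), "count")
})

test_that("proportion interval width shrinks as 1/sqrt(total)", {
  w <- function(total) {
    ci <- proportion_ci(round(0.3 * total), total)
    ci$upper - ci$lower
  }
  expect_equal(w(1000) / w(4000), 2, tolerance = 0.02)
})
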