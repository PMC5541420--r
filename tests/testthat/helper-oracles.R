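# Independent oracles used by the property-style tests.

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments, mid-p convention: P(W < w) + P(W = w)/2 where W is the
# smaller signed-rank sum.  The uncorrected normal approximation estimates
# the mid-p, so this is the continuity-matched exact reference.
exact_wilcoxon_p <- function(available, ideal) {
  d <- available - ideal
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  total <- sum(r)
  w_obs <- min(sum(r[d > 0]), total - sum(r[d > 0]))
  ws <- enumerate_min_ranksums(r)
  mean(ws < w_obs) + mean(ws == w_obs) / 2
}

# Distribution of the smaller signed-rank sum over all sign assignments.
enumerate_min_ranksums <- function(r) {
  n <- length(r)
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  apply(signs, 1L, function(s) {
    pos <- sum(r[s])
    min(pos, total - pos)
  })
}

# Within-row permutation null for the Friedman statistic.
friedman_perm_p <- function(m, n_perm = 10000, seed = 99) {
  stat_of <- function(mm) {
    ranks <- t(apply(mm, 1L, rank))
    rj <- colSums(ranks)
    n <- nrow(mm); k <- ncol(mm)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  obs <- stat_of(m)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- t(apply(m, 1L, sample))
    if (stat_of(perm) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Tiny valid study used by IO and validation tests.
tiny_study <- function() {
  facilities <- data.frame(
    facility_id = c("A", "B"), state = c("Morelos", "Hidalgo"),
    locality = c("urban", "rural"),
    headcount_physician = c(2L, 1L), headcount_nurse = c(3L, 0L),
    headcount_hp = c(0L, 0L), stringsAsFactors = FALSE
  )
  population <- data.frame(
    facility_id = rep(c("A", "B"), each = 2),
    age_group = rep(c("kids", "adults"), 2),
    n = c(100L, 200L, 50L, 80L), stringsAsFactors = FALSE
  )
  times <- expand.grid(
    facility_id = c("A", "B"), age_group = c("kids", "adults"),
    cadre = c("physician", "nurse", "health_promoter"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  times$minutes_used <- seq(10, by = 5, length.out = nrow(times))
  times$minutes_required <- times$minutes_used * 1.5
  hrgap_study(facilities, population, times)
}
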