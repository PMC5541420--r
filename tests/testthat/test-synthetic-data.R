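test_that("the generator is deterministic and schema-valid", {
  cfg <- generator_config()
  s1 <- generate_study(cfg, seed = 7)
  s2 <- generate_study(cfg, seed = 7)
  expect_identical(s1$facilities, s2$facilities)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$times, s2$times)
  s3 <- generate_study(cfg, seed = 8)
  expect_false(identical(s1$times, s3$times))
  expect_equal(nrow(validate_study(s1)), 0)
})

test_that("default world matches the stated study structure", {
  study <- generate_study(generator_config(), seed = 3)
  fac <- study$facilities
  expect_equal(sum(fac$locality == "urban"), 12)
  expect_equal(sum(fac$locality == "rural"), 8)
  expect_equal(sum(study$population$n), 268527)
  urb <- fac$facility_id[fac$locality == "urban"]
  share <- sum(study$population$n[study$population$facility_id %in% urb]) /
    sum(study$population$n)
  expect_lt(abs(share - 0.87), 0.02)
  expect_equal(nrow(unique(study$activities[c("age_group", "activity_id")])), 99)
  expect_true(all(study$times$minutes_used >= 0))
  # required exceeds used on average
  expect_gt(mean(study$times$minutes_required - study$times$minutes_used), 0)
})

test_that("per-activity minutes reduce back to the group targets", {
  cfg <- generator_config()
  red <- activities_to_group_minutes(generate_study(cfg, seed = 1)$activities)
  gt <- cfg$group_times
  for (g in gt$age_group) {
    tu_p <- red$minutes_used[red$age_group == g & red$cadre == "physician"]
    if (length(tu_p))
      expect_equal(tu_p, gt$tu_physician[gt$age_group == g], tolerance = 1e-9)
  }
})

test_that("grand time medians stay near the calibration targets", {
  # 500 facilities shrink the Monte Carlo error of the pooled median
  cfg <- generator_config(n_urban = 300, n_rural = 200)
  ts <- time_summary(generate_study(cfg, seed = 42))
  all_row <- ts[ts$age_group == "all_groups", ]
  expect_lt(abs(all_row$tu_total - 73) / 73, 0.10)
  expect_lt(abs(all_row$tr_total - 105) / 105, 0.10)
})

test_that("facility sub-streams survive a change in facility count", {
  big <- generate_study(generator_config(), seed = 5)
  small <- generate_study(generator_config(n_urban = 6, n_rural = 4), seed = 5)
  shared <- intersect(big$facilities$facility_id, small$facilities$facility_id)
  expect_gte(length(shared), 10)
  tb <- big$times[big$times$facility_id %in% shared, ]
  tsm <- small$times[small$times$facility_id %in% shared, ]
  ord <- function(d) d[order(d$facility_id, d$age_group, d$cadre), ]
  expect_equal(ord(tb)$minutes_used, ord(tsm)$minutes_used)
})

test_that("inflation 1 with zero noise makes the two channels identical", {
  gt <- generator_config()$group_times
  gt[c("tr_physician", "tr_nurse", "tr_hp")] <-
    gt[c("tu_physician", "tu_nurse", "tu_hp")]
  cfg <- generator_config(group_times = gt, tr_noise_shape = Inf)
  supply <- estimate_supply(generate_study(cfg, seed = 4))
  expect_equal(supply$is_tr_hours, supply$is_tu_hours, tolerance = 1e-12)
})

test_that("full-pipeline parameter recovery on generated data", {
  cfg <- generator_config(n_urban = 120, n_rural = 80)
  study <- generate_study(cfg, seed = 2024)
  gt <- cfg$group_times
  tim <- study$times
  # each positive group x cadre cell median within 2 SE of its target
  z <- c()
  for (g in gt$age_group) {
    for (cad in c("physician", "nurse", "health_promoter")) {
      target <- gt[[paste0("tu_", sub("health_promoter", "hp", cad))]][gt$age_group == g]
      if (target == 0) next
      x <- tim$minutes_used[tim$age_group == g & tim$cadre == cad]
      # asymptotic SE of the sample median of a gamma with median = target
      shape <- cfg$time_shape
      scale <- target / qgamma(0.5, shape)
      f_med <- stats::dgamma(target, shape = shape, scale = scale)
      se <- 1 / (2 * f_med * sqrt(length(x)))
      z <- c(z, (stats::median(x) - target) / se)
    }
  }
  expect_gte(mean(abs(z) <= 2), 0.9)   # ~95% coverage expected at 2 SE
  expect_lt(max(abs(z)), 4)
  # pooled normalized draws recover the configured gamma shape within 15%
  for (cad in c("physician", "nurse", "health_promoter")) {
    col <- paste0("tu_", sub("health_promoter", "hp", cad))
    targets <- setNames(gt[[col]], gt$age_group)
    x <- tim[tim$cadre == cad & targets[tim$age_group] > 0, ]
    norm <- x$minutes_used / targets[x$age_group]
    fit <- fit_gamma(as.numeric(norm))
    expect_lt(abs(fit$alpha - cfg$time_shape) / cfg$time_shape, 0.15)
  }
})

test_that("degenerate fixtures carry their stated truths", {
  cfg <- estimation_config()
  nog <- fte_gap(estimate_supply(degenerate_study("no_gap")), cfg)
  expect_true(all(nog$gap_tu_fte == 0))
  expect_true(all(nog$gap_tr_fte == 0))
  ssum <- summarise_supply(estimate_supply(degenerate_study("no_gap")))
  expect_true(all(ssum$wilcoxon_tu_skipped))

  allg <- estimate_supply(degenerate_study("all_gap"))
  phys <- allg[allg$cadre == "physician", ]
  res <- wilcoxon_signed_rank(phys$as_hours, phys$is_tu_hours)
  expect_lt(res$p_value, 0.01)
  expect_true(all(supply_gap(phys$as_hours, phys$is_tu_hours) < 0))

  zp <- estimate_supply(degenerate_study("zero_promoters"))
  hp <- zp[zp$cadre == "health_promoter", ]
  expect_equal(aggregate_median(hp$as_hours), 0)
  expect_true(all(supply_gap(hp$as_hours, hp$is_tu_hours) < 0))
})

test_that("generator_config rejects invalid worlds", {
  expect_error(generator_config(urban_share = 1.2), "urban_share")
  expect_error(generator_config(time_shape = 0), "positive")
  expect_error(generator_config(n_urban = 1, n_rural = 0), "at least 2")
  gt <- generator_config()$group_times
  gt$population_share <- gt$population_share * 2
  expect_error(generator_config(group_times = gt), "sum to 1")
})
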