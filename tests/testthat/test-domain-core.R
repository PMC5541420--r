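test_that("available supply accounting follows the 200 x 6 convention", {
  cfg <- estimation_config()
  expect_equal(available_supply_hours(10, cfg), 12000)
  expect_equal(available_supply_hours(0, cfg), 0)
  expect_equal(available_supply_hours(118, cfg), 141600)
  expect_equal(available_supply_hours(c(1, 2, 3), cfg), c(1200, 2400, 3600))
  expect_error(available_supply_hours(-1, cfg), "non-negative")
  # a utilization factor < 1 shrinks available time proportionally
  expect_equal(available_supply_hours(10, estimation_config(utilization = 0.5)),
               6000)
})

test_that("estimation_config validates its invariants", {
  expect_error(estimation_config(working_days_per_year = 0), "positive")
  expect_error(estimation_config(utilization = 0), "utilization")
  expect_error(estimation_config(utilization = 1.2), "utilization")
  cfg <- estimation_config()
  expect_equal(cfg$working_days_per_year * cfg$hours_per_day,
               cfg$annual_fte_hours)
})

test_that("ideal supply converts minutes x population to annual hours", {
  expect_equal(ideal_supply_hours(c(g = 60), c(g = 1200)), 1200)
  expect_equal(ideal_supply_hours(c(g = 73), c(g = 268527)), 326707.85)
  expect_equal(ideal_supply_hours(c(a = 30, b = 45), c(a = 0, b = 0)), 0)
  expect_error(ideal_supply_hours(c(a = 10), c(b = 5)), "no population entry")
  expect_error(ideal_supply_hours(c(a = -1), c(a = 5)), "non-negative")
})

test_that("ideal supply is linear in population and monotone in minutes", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:8, 1)
    g <- paste0("g", seq_len(k))
    tu <- setNames(runif(k, 0, 120), g)
    tr <- tu + runif(k, 0, 60)  # required >= used everywhere
    pop <- setNames(sample(0:5000, k), g)
    expect_equal(ideal_supply_hours(tu, 2 * pop), 2 * ideal_supply_hours(tu, pop))
    expect_gte(ideal_supply_hours(tr, pop), ideal_supply_hours(tu, pop))
  }
})

test_that("FTE conversion inverts the supply accounting", {
  cfg <- estimation_config()
  expect_equal(hours_to_fte(12000, cfg), 10)
  expect_equal(hours_to_fte(0, cfg), 0)
  expect_equal(round_half_up(hours_to_fte(16749, cfg)), 14.0)
  expect_error(hours_to_fte(-5, cfg), "non-negative")
  for (n in 0:25) expect_equal(hours_to_fte(available_supply_hours(n, cfg), cfg), n)
})

test_that("supply gap is the signed available-minus-ideal difference", {
  expect_equal(supply_gap(12000, 22624.2), -10624.2)
  expect_equal(supply_gap(1800, 4079.7), -2279.7)
  expect_equal(supply_gap(5, 5), 0)
  expect_equal(supply_gap(c(1, 2), c(2, 1)), c(-1, 1))
})

test_that("aggregate_median matches the sort-based oracle", {
  expect_equal(aggregate_median(42), 42)
  expect_equal(aggregate_median(c(1, 2, 3, 4)), 2.5)
  expect_error(aggregate_median(numeric(0)), "empty")
  expect_error(aggregate_median(c(1, NA)), "missing")
  expect_equal(aggregate_median(c(NA, 3, 1), na.rm = TRUE), 2)
  set.seed(7)
  for (i in 1:50) {
    x <- runif(sample(1:25, 1), -100, 100)
    expect_equal(aggregate_median(x), stats::median(x))
  }
})

test_that("median time differences and half-up rounding behave as printed", {
  expect_equal(median_time_difference(73, 105), -32)
  expect_equal(median_time_difference(55.5, 90), -34.5)
  expect_equal(median_time_difference(10, 10), 0)
  expect_equal(round_half_up(13.75), 13.8)   # round() would give 13.8 vs 13.7 issue
  expect_equal(round_half_up(10.45), 10.5)
  expect_equal(round_half_up(-13.75), -13.8)
  expect_equal(round_half_up(56.47, 0), 56)
})

test_that("per-activity minutes reduce to group x cadre totals", {
  acts <- data.frame(
    activity_id = c("a1", "a2", "a3", "a1"),
    age_group = c("kids", "kids", "kids", "adults"),
    cadre = c("physician", "physician", "nurse", "nurse"),
    minutes_used = c(10, 20, 5, 7),
    minutes_required = c(15, 25, 6, 9),
    stringsAsFactors = FALSE
  )
  red <- activities_to_group_minutes(acts)
  phys_kids <- red[red$age_group == "kids" & red$cadre == "physician", ]
  expect_equal(phys_kids$minutes_used, 30)
  expect_equal(phys_kids$minutes_required, 40)
  expect_equal(nrow(red), 3)
  acts_dup <- rbind(acts, acts[1, ])
  expect_error(activities_to_group_minutes(acts_dup), "duplicate")
})
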