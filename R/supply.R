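#' Estimate available and ideal supply per facility and cadre
#'
#' Applies the supply accounting to every facility x cadre cell:
#' available supply `As` from headcounts, ideal supply from the two time
#' channels (`Is_tu` from time used, `Is_tr` from time required) weighted by
#' the facility's attended population.
#'
#' @param study An [hrgap_study()].
#' @param config An [estimation_config()].
#' @return Data frame with one row per facility x cadre: `facility_id`,
#'   `locality`, `cadre`, `headcount`, `as_hours`, `is_tu_hours`,
#'   `is_tr_hours`.
#' @export
estimate_supply <- function(study, config = estimation_config()) {
  stopifnot(inherits(config, "estimation_config"))
  fac <- study$facilities
  pop <- study$population
  tim <- study$times

  rows <- vector("list", nrow(fac) * length(CADRES))
  k <- 0L
  for (i in seq_len(nrow(fac))) {
    fid <- fac$facility_id[i]
    fpop <- setNames(pop$n[pop$facility_id == fid],
                     pop$age_group[pop$facility_id == fid])
    ftim <- tim[tim$facility_id == fid, , drop = FALSE]
    for (cad in CADRES) {
      ct <- ftim[ftim$cadre == cad, , drop = FALSE]
      hc <- fac[[HEADCOUNT_COLS[[cad]]]][i]
      is_tu <- if (nrow(ct)) {
        ideal_supply_hours(setNames(ct$minutes_used, ct$age_group), fpop)
      } else 0
      is_tr <- if (nrow(ct)) {
        ideal_supply_hours(setNames(ct$minutes_required, ct$age_group), fpop)
      } else 0
      k <- k + 1L
      rows[[k]] <- data.frame(
        facility_id = fid, locality = fac$locality[i], cadre = cad,
        headcount = hc,
        as_hours = available_supply_hours(hc, config),
        is_tu_hours = is_tu, is_tr_hours = is_tr,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Express supply estimates as full-time equivalents and gaps
#'
#' @param supply Output of [estimate_supply()].
#' @param config An [estimation_config()].
#' @return The input with columns `as_fte`, `is_tu_fte`, `is_tr_fte`,
#'   `gap_tu_fte` (= available - ideal from time used) and `gap_tr_fte`
#'   appended.
#' @export
fte_gap <- function(supply, config = estimation_config()) {
  supply$as_fte <- hours_to_fte(supply$as_hours, config)
  supply$is_tu_fte <- hours_to_fte(supply$is_tu_hours, config)
  supply$is_tr_fte <- hours_to_fte(supply$is_tr_hours, config)
  supply$gap_tu_fte <- supply_gap(supply$as_fte, supply$is_tu_fte)
  supply$gap_tr_fte <- supply_gap(supply$as_fte, supply$is_tr_fte)
  supply
}

#' Stratum-level supply summary with paired tests
#'
#' Aggregates facility x cadre supply estimates into strata (urban, rural,
#' and their union), reporting totals, medians, median gaps, and the paired
#' nonparametric comparisons: Wilcoxon signed-rank of `As` against each
#' ideal-supply channel and the Friedman test across the three matched
#' columns (`As`, `Is_tu`, `Is_tr`).  Strata with too few usable pairs are
#' reported with `NA` p-values (test skipped), never dropped.
#'
#' @param supply Output of [estimate_supply()].
#' @return Data frame with one row per stratum x cadre.
#' @export
summarise_supply <- function(supply) {
  strata <- list(urban = "urban", rural = "rural",
                 total = c("urban", "rural"))
  rows <- list()
  for (sname in names(strata)) {
    sub <- supply[supply$locality %in% strata[[sname]], , drop = FALSE]
    for (cad in CADRES) {
      d <- sub[sub$cadre == cad, , drop = FALSE]
      if (!nrow(d)) next
      w_tu <- wilcoxon_signed_rank(d$as_hours, d$is_tu_hours)
      w_tr <- wilcoxon_signed_rank(d$as_hours, d$is_tr_hours)
      fr <- friedman_rank_test(cbind(As = d$as_hours, Is_tu = d$is_tu_hours,
                                     Is_tr = d$is_tr_hours))
      med_as <- aggregate_median(d$as_hours)
      med_tu <- aggregate_median(d$is_tu_hours)
      med_tr <- aggregate_median(d$is_tr_hours)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = sname, cadre = cad, n = nrow(d),
        total_as = sum(d$as_hours),
        total_is_tu = sum(d$is_tu_hours),
        total_is_tr = sum(d$is_tr_hours),
        median_as = med_as, median_is_tu = med_tu, median_is_tr = med_tr,
        gap_tu = supply_gap(med_as, med_tu),
        gap_tr = supply_gap(med_as, med_tr),
        wilcoxon_p_tu = w_tu$p_value, wilcoxon_p_tr = w_tr$p_value,
        friedman_p = fr$p_value,
        wilcoxon_tu_skipped = w_tu$skipped, wilcoxon_tr_skipped = w_tr$skipped,
        friedman_skipped = fr$skipped,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-facility FTE table with stratum medians
#'
#' Renders the FTE view of the gap analysis for one cadre: one row per
#' facility (available, ideal-from-time-used, ideal-from-time-required FTE)
#' followed by the urban, rural and general medians and median gaps.
#'
#' @param supply Output of [estimate_supply()].
#' @param cadre One of `"physician"`, `"nurse"`, `"health_promoter"`.
#' @param config An [estimation_config()].
#' @return List with `facilities` (per-facility FTE data frame) and
#'   `medians` (per-stratum medians with gaps, rounded half-up to 1 decimal).
#' @export
fte_table <- function(supply, cadre = "physician", config = estimation_config()) {
  stopifnot(cadre %in% CADRES)
  d <- fte_gap(supply[supply$cadre == cadre, , drop = FALSE], config)
  fac <- data.frame(
    facility_id = d$facility_id, locality = d$locality,
    available_fte = d$as_fte, ideal_tu_fte = d$is_tu_fte,
    ideal_tr_fte = d$is_tr_fte, stringsAsFactors = FALSE
  )
  med_rows <- list()
  for (s in list(c("urban"), c("rural"), c("urban", "rural"))) {
    sub <- fac[fac$locality %in% s, , drop = FALSE]
    if (!nrow(sub)) next
    label <- if (length(s) == 2L) "general" else s
    m_av <- aggregate_median(sub$available_fte)
    m_tu <- aggregate_median(sub$ideal_tu_fte)
    m_tr <- aggregate_median(sub$ideal_tr_fte)
    med_rows[[length(med_rows) + 1L]] <- data.frame(
      stratum = label,
      available_fte = round_half_up(m_av),
      ideal_tu_fte = round_half_up(m_tu),
      gap_tu_fte = round_half_up(supply_gap(m_av, m_tu)),
      ideal_tr_fte = round_half_up(m_tr),
      gap_tr_fte = round_half_up(supply_gap(m_av, m_tr)),
      stringsAsFactors = FALSE
    )
  }
  meds <- do.call(rbind, med_rows)
  rownames(meds) <- NULL
  list(facilities = fac, medians = meds)
}

#' Median service-time summary by age group
#'
#' Summarises per-person annual minutes across facilities: for every age
#' group, the median time used and time required per cadre, a total column,
#' and the used-minus-required differences.  Two total aggregations exist
#' because medians are not additive:
#'
#' * `total` (canonical): median across facilities of the facility-level
#'   cadre-summed minutes;
#' * `total_som`: sum of the three cadre medians.
#'
#' The `all_groups` row pools every facility x age-group cell.
#'
#' @param study An [hrgap_study()].
#' @return Data frame with one row per age group plus an `all_groups` row;
#'   columns `tu_*`/`tr_*` for each cadre and total, and `diff_*`
#'   (used - required).
#' @export
time_summary <- function(study) {
  tim <- study$times
  groups <- unique(tim$age_group)
  cadre_cols <- c(physician = "physician", nurse = "nurse",
                  health_promoter = "hp")

  summarise_cells <- function(sub) {
    # cadre-summed totals per facility x age-group cell
    key <- paste(sub$facility_id, sub$age_group)
    tot_u <- tapply(sub$minutes_used, key, sum)
    tot_r <- tapply(sub$minutes_required, key, sum)
    row <- list(
      tu_total = aggregate_median(as.numeric(tot_u)),
      tr_total = aggregate_median(as.numeric(tot_r))
    )
    som_u <- 0; som_r <- 0
    for (cad in CADRES) {
      cd <- sub[sub$cadre == cad, , drop = FALSE]
      mu <- if (nrow(cd)) aggregate_median(cd$minutes_used) else NA_real_
      mr <- if (nrow(cd)) aggregate_median(cd$minutes_required) else NA_real_
      row[[paste0("tu_", cadre_cols[[cad]])]] <- mu
      row[[paste0("tr_", cadre_cols[[cad]])]] <- mr
      som_u <- som_u + if (is.na(mu)) 0 else mu
      som_r <- som_r + if (is.na(mr)) 0 else mr
    }
    row$tu_total_som <- som_u
    row$tr_total_som <- som_r
    row
  }

  rows <- list()
  for (g in groups) {
    sub <- tim[tim$age_group == g, , drop = FALSE]
    row <- summarise_cells(sub)
    rows[[length(rows) + 1L]] <- data.frame(age_group = g, row,
                                            stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(age_group = "all_groups",
                                          summarise_cells(tim),
                                          stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$diff_total <- median_time_difference(out$tu_total, out$tr_total)
  out$diff_physician <- median_time_difference(out$tu_physician, out$tr_physician)
  out$diff_nurse <- median_time_difference(out$tu_nurse, out$tr_nurse)
  out$diff_hp <- median_time_difference(out$tu_hp, out$tr_hp)
  rownames(out) <- NULL
  out
}

#' Workforce composition and attended-population shares
#'
#' Proportions with normal-approximation confidence intervals for the cadre
#' composition of the service-delivery workforce (from facility headcounts)
#' and the urban share of the attended population.
#'
#' @param study An [hrgap_study()].
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per quantity: `what`, `count`, `total`,
#'   `point`, `lower`, `upper` (percent scale).
#' @export
composition_summary <- function(study, level = 0.95) {
  fac <- study$facilities
  counts <- vapply(CADRES, function(cad) sum(fac[[HEADCOUNT_COLS[[cad]]]]),
                   numeric(1))
  total_staff <- sum(counts)
  pop_by_loc <- tapply(study$population$n,
                       fac$locality[match(study$population$facility_id,
                                          fac$facility_id)],
                       sum)
  total_pop <- sum(study$population$n)
  rows <- list()
  for (cad in CADRES) {
    ci <- proportion_ci(counts[[cad]], total_staff, level)
    rows[[length(rows) + 1L]] <- data.frame(
      what = paste0("share_", cad), count = counts[[cad]],
      total = total_staff, point = ci$point, lower = ci$lower,
      upper = ci$upper, stringsAsFactors = FALSE
    )
  }
  urban_n <- if ("urban" %in% names(pop_by_loc)) pop_by_loc[["urban"]] else 0
  ci <- proportion_ci(urban_n, total_pop, level)
  rows[[length(rows) + 1L]] <- data.frame(
    what = "attended_urban_share", count = urban_n, total = total_pop,
    point = ci$point, lower = ci$lower, upper = ci$upper,
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
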