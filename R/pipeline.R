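#' Run the complete gap-estimation pipeline
#'
#' Chains every stage: validation, supply accounting (available and ideal
#' hours per facility x cadre), FTE conversion and gaps, the age-group time
#' summary, stratum-level comparisons with Wilcoxon/Friedman tests, the
#' workforce-composition proportions, and the gamma sensitivity screen.
#' Optionally writes tidy CSVs and plain-text renderings of the three report
#' tables.
#'
#' @param input An [hrgap_study()], a directory of study CSVs, or a
#'   [generator_config()] (in which case `seed` is used to simulate).
#' @param output_dir Optional directory for tidy CSV + text outputs.
#' @param config An [estimation_config()].
#' @param seed Seed used when `input` is a generator configuration.
#' @param quiet Suppress progress logging to stderr.
#' @return Object of class `hrgap_report`: list with `study`, `supply`,
#'   `fte`, `time_summary`, `supply_summary`, `fte_tables` (per cadre),
#'   `composition`, `sensitivity`, `violations`.
#' @export
run_pipeline <- function(input, output_dir = NULL,
                         config = estimation_config(), seed = 1L,
                         quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))

  study <- if (inherits(input, "hrgap_study")) {
    input
  } else if (inherits(input, "generator_config")) {
    log_msg("simulate: generating synthetic study (seed %d)", as.integer(seed))
    generate_study(input, seed = seed)
  } else if (is.character(input) && length(input) == 1L) {
    log_msg("read: loading study from %s", input)
    read_study(input, check = FALSE)
  } else {
    stop("run_pipeline: 'input' must be a study, a directory, or a generator_config")
  }

  violations <- validate_study(study)
  if (nrow(violations)) {
    stop("run_pipeline: input validation failed with ", nrow(violations),
         " violation(s); first: [", violations$file[1], "] row ",
         violations$row[1], ", ", violations$column[1], ": ",
         violations$message[1])
  }
  log_msg("validate: %d facilities, %d population rows, %d time rows, 0 violations",
          nrow(study$facilities), nrow(study$population), nrow(study$times))

  supply <- estimate_supply(study, config)
  fte <- fte_gap(supply, config)
  log_msg("estimate: %d facility x cadre supply rows", nrow(supply))

  tsum <- time_summary(study)
  ssum <- summarise_supply(supply)
  log_msg("compare: %d stratum x cadre summary rows", nrow(ssum))

  ftabs <- setNames(lapply(CADRES, function(cad) fte_table(supply, cad, config)),
                    CADRES)
  comp <- composition_summary(study)
  sens <- gamma_sensitivity_report(study)
  log_msg("sensitivity: %d fitted strata, median-safe in %d",
          sum(!is.na(sens$alpha)), sum(sens$skew_ok, na.rm = TRUE))

  report <- structure(
    list(study = study, supply = supply, fte = fte, time_summary = tsum,
         supply_summary = ssum, fte_tables = ftabs, composition = comp,
         sensitivity = sens, violations = violations,
         config = config),
    class = "hrgap_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir, quiet = quiet)
  report
}

#' Write a report bundle to disk
#'
#' Tidy CSVs (`supply.csv`, `fte.csv`, `time_summary.csv`,
#' `supply_summary.csv`, `composition.csv`, `sensitivity.csv`) plus
#' plain-text renderings of the three report tables.
#'
#' @param report An `hrgap_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param quiet Suppress logging.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, quiet = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  w(report$supply, "supply.csv")
  w(report$fte, "fte.csv")
  w(report$time_summary, "time_summary.csv")
  w(report$supply_summary, "supply_summary.csv")
  w(report$composition, "composition.csv")
  w(report$sensitivity, "sensitivity.csv")
  writeLines(render_time_table(report$time_summary),
             file.path(dir, "table_times.txt"))
  writeLines(render_supply_table(report$supply_summary),
             file.path(dir, "table_supply.txt"))
  writeLines(render_fte_table(report$fte_tables),
             file.path(dir, "table_fte.txt"))
  if (!quiet) message(sprintf("report: wrote 6 CSVs and 3 tables to %s", dir))
  invisible(dir)
}

fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", round_half_up(x, 1)))
fmt_p <- function(p, skipped) ifelse(skipped, "NA", sprintf("%.4f", p))

# Plain-ASCII rendering of the age-group time summary.
render_time_table <- function(ts) {
  header <- sprintf("%-22s %8s %8s %8s %8s %8s %8s %8s %8s %8s",
                    "age_group", "tu_tot", "tu_phys", "tu_nurse", "tu_hp",
                    "tr_tot", "tr_phys", "tr_nurse", "tr_hp", "diff")
  rows <- vapply(seq_len(nrow(ts)), function(i) {
    sprintf("%-22s %8s %8s %8s %8s %8s %8s %8s %8s %8s",
            ts$age_group[i], fmt1(ts$tu_total[i]), fmt1(ts$tu_physician[i]),
            fmt1(ts$tu_nurse[i]), fmt1(ts$tu_hp[i]), fmt1(ts$tr_total[i]),
            fmt1(ts$tr_physician[i]), fmt1(ts$tr_nurse[i]), fmt1(ts$tr_hp[i]),
            fmt1(ts$diff_total[i]))
  }, character(1))
  c("Median per-person annual service minutes by age group", header, rows)
}

# Stratum x cadre hours with test p-values.
render_supply_table <- function(ss) {
  header <- sprintf("%-7s %-16s %3s %12s %12s %12s %10s %10s %9s %9s %9s",
                    "stratum", "cadre", "n", "total_As", "total_Is_tu",
                    "total_Is_tr", "median_As", "gap_tu", "p_wilc_tu",
                    "p_wilc_tr", "p_friedman")
  rows <- vapply(seq_len(nrow(ss)), function(i) {
    sprintf("%-7s %-16s %3d %12.1f %12.1f %12.1f %10.1f %10.1f %9s %9s %9s",
            ss$stratum[i], ss$cadre[i], ss$n[i], ss$total_as[i],
            ss$total_is_tu[i], ss$total_is_tr[i], ss$median_as[i],
            ss$gap_tu[i],
            fmt_p(ss$wilcoxon_p_tu[i], ss$wilcoxon_tu_skipped[i]),
            fmt_p(ss$wilcoxon_p_tr[i], ss$wilcoxon_tr_skipped[i]),
            fmt_p(ss$friedman_p[i], ss$friedman_skipped[i]))
  }, character(1))
  c("Available vs ideal supply (annual hours) by stratum and cadre",
    header, rows)
}

# Per-facility FTE with stratum medians, one block per cadre.
render_fte_table <- function(ftabs) {
  out <- character(0)
  for (cad in names(ftabs)) {
    ft <- ftabs[[cad]]
    out <- c(out, sprintf("FTE (available vs ideal): %s", cad),
             sprintf("%-14s %-7s %10s %10s %10s", "facility", "locality",
                     "available", "ideal_tu", "ideal_tr"))
    out <- c(out, vapply(seq_len(nrow(ft$facilities)), function(i) {
      sprintf("%-14s %-7s %10s %10s %10s",
              ft$facilities$facility_id[i], ft$facilities$locality[i],
              fmt1(ft$facilities$available_fte[i]),
              fmt1(ft$facilities$ideal_tu_fte[i]),
              fmt1(ft$facilities$ideal_tr_fte[i]))
    }, character(1)))
    out <- c(out, vapply(seq_len(nrow(ft$medians)), function(i) {
      sprintf("%-14s %-7s %10s %10s %10s",
              paste0("median_", ft$medians$stratum[i]), "",
              fmt1(ft$medians$available_fte[i]),
              fmt1(ft$medians$ideal_tu_fte[i]),
              fmt1(ft$medians$ideal_tr_fte[i]))
    }, character(1)), "")
  }
  out
}

#' @export
print.hrgap_report <- function(x, ...) {
  cat("Workforce gap report\n")
  cat(sprintf("  facilities : %d\n", nrow(x$study$facilities)))
  cat(sprintf("  violations : %d\n", nrow(x$violations)))
  gm <- x$fte_tables$physician$medians
  gen <- gm[gm$stratum == "general", , drop = FALSE]
  if (nrow(gen)) {
    cat(sprintf("  physicians : available %.1f FTE, ideal %.1f (tu) / %.1f (tr), gap %.1f / %.1f\n",
                gen$available_fte, gen$ideal_tu_fte, gen$ideal_tr_fte,
                gen$gap_tu_fte, gen$gap_tr_fte))
  }
  safe <- x$sensitivity$skew_ok
  cat(sprintf("  median-safe strata (gamma alpha >= 1.33): %d of %d fitted\n",
              sum(safe, na.rm = TRUE), sum(!is.na(safe))))
  invisible(x)
}
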