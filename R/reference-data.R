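#' Published summary tables of the 2009 Mexican primary-care workforce study
#'
#' Transcriptions of the printed summary tables of the cross-sectional study
#' of 20 Mexican primary health facilities (12 urban, 8 rural; 2009) whose
#' design this package implements.  The facility-level elicitation data were
#' never deposited; these stratum-level summaries are the published surface
#' and serve as calibration targets for the synthetic generator and as
#' inputs to the desk-scale acceptance checks.
#'
#' @return A named list of data frames:
#' * `age_groups` — per age group: activity count, attended population, and
#'   median per-person annual minutes (time used `tu_*` and time required
#'   `tr_*`) by cadre, plus an `all_groups` row of pooled medians.
#' * `facility_fte` — per facility: available and ideal supply (both time
#'   channels) expressed in FTE, for physicians and (urban only) health
#'   promoters.
#' * `supply_hours` — per stratum x cadre: total and median annual hours of
#'   available/ideal supply and the printed Wilcoxon/Friedman p-values.
#' * `workforce` — staff-category counts and attended-population counts.
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", "reference", package = "hrgap",
                     mustWork = TRUE)
  read1 <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(
    age_groups = read1("age_groups.csv"),
    facility_fte = read1("facility_fte.csv"),
    supply_hours = read1("supply_hours.csv"),
    workforce = read1("workforce.csv")
  )
}

# Canonical 10 age groups (all_groups row excluded).
reference_age_groups <- function() {
  ag <- reference_tables()$age_groups
  ag[ag$age_group != "all_groups", , drop = FALSE]
}
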