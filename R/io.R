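#' Write a study to a directory of CSV files
#'
#' Emits `facilities.csv`, `population.csv`, `times.csv`, optionally
#' `activities.csv`, and — when the study carries generator metadata — a
#' `manifest.yaml` recording the configuration and seed.
#'
#' @param study An [hrgap_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  w(study$facilities, "facilities.csv")
  w(study$population, "population.csv")
  w(study$times, "times.csv")
  if (!is.null(study$activities)) w(study$activities, "activities.csv")
  cfg <- attr(study, "config")
  if (!is.null(cfg)) {
    manifest <- list(
      seed = attr(study, "seed"),
      n_urban = cfg$n_urban, n_rural = cfg$n_rural,
      time_shape = cfg$time_shape, tr_noise_shape = cfg$tr_noise_shape,
      total_population = cfg$total_population, urban_share = cfg$urban_share,
      concentration = cfg$concentration,
      include_activities = cfg$include_activities
    )
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}

#' Read a study from a directory of CSV files
#'
#' Counterpart of [write_study()]; expects UTF-8 CSVs with header rows.
#'
#' @param dir Directory containing `facilities.csv`, `population.csv`,
#'   `times.csv` and optionally `activities.csv`.
#' @param check Validate after reading (default TRUE).
#' @return An [hrgap_study()].
#' @export
read_study <- function(dir, check = TRUE) {
  if (!dir.exists(dir)) stop("read_study: no such directory: ", dir)
  need <- c("facilities.csv", "population.csv", "times.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("read_study: missing input file(s): ", paste(missing, collapse = ", "))
  r <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  act_path <- file.path(dir, "activities.csv")
  hrgap_study(
    facilities = r("facilities.csv"),
    population = r("population.csv"),
    times = r("times.csv"),
    activities = if (file.exists(act_path)) r("activities.csv"),
    check = check
  )
}

#' Validate the CSV inputs in a directory
#'
#' Reads the study tables without failing and returns the full violation
#' report (see [validate_study()]).
#'
#' @param dir Input directory.
#' @return Violation data frame (zero rows when valid), with attribute
#'   `activity_total`.
#' @export
validate_inputs <- function(dir) {
  study <- read_study(dir, check = FALSE)
  validate_study(study)
}
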