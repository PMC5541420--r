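#' Assemble a facility study
#'
#' Bundles the three (optionally four) tables the pipeline consumes into a
#' single validated object.  The schemas mirror the CSV interchange format
#' (see [read_study()] / [write_study()]):
#'
#' * `facilities`: `facility_id`, `state`, `locality` (`urban`/`rural`),
#'   `headcount_physician`, `headcount_nurse`, `headcount_hp`.
#' * `population`: `facility_id`, `age_group`, `n` — attended individuals.
#' * `times`: `facility_id`, `age_group`, `cadre`, `minutes_used`,
#'   `minutes_required` — per-person annual service minutes.
#' * `activities` (optional): `activity_id`, `age_group`, `cadre`,
#'   `minutes_used`, `minutes_required` — study-level per-activity minutes.
#'
#' @param facilities,population,times,activities Data frames as above.
#' @param check Validate invariants (default TRUE); on violation the first
#'   problems are reported and construction fails.
#' @return An object of class `hrgap_study` (a named list of data frames).
#' @export
hrgap_study <- function(facilities, population, times, activities = NULL,
                        check = TRUE) {
  study <- structure(
    list(facilities = as.data.frame(facilities),
         population = as.data.frame(population),
         times = as.data.frame(times),
         activities = if (!is.null(activities)) as.data.frame(activities)),
    class = "hrgap_study"
  )
  if (check) {
    v <- validate_study(study)
    if (nrow(v)) {
      show <- utils::head(v, 5L)
      stop("hrgap_study: invalid study data:\n",
           paste(sprintf("  [%s] row %s, %s: %s", show$file, show$row,
                         show$column, show$message), collapse = "\n"),
           if (nrow(v) > 5L) sprintf("\n  ... and %d more", nrow(v) - 5L))
    }
  }
  study
}

#' @export
print.hrgap_study <- function(x, ...) {
  loc <- table(x$facilities$locality)
  cat(sprintf("Facility study: %d facilities (%d urban, %d rural)\n",
              nrow(x$facilities),
              if ("urban" %in% names(loc)) loc[["urban"]] else 0L,
              if ("rural" %in% names(loc)) loc[["rural"]] else 0L))
  cat(sprintf("  attended population : %s\n",
              format(sum(x$population$n), big.mark = " ")))
  cat(sprintf("  age groups          : %d\n",
              length(unique(x$population$age_group))))
  cat(sprintf("  time records        : %d\n", nrow(x$times)))
  if (!is.null(x$activities))
    cat(sprintf("  activities          : %d\n",
                length(unique(paste(x$activities$age_group,
                                    x$activities$activity_id)))))
  invisible(x)
}

# One validation violation row.
violation <- function(file, row, column, message) {
  data.frame(file = file, row = as.integer(row), column = column,
             message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(file = character(), row = integer(), column = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate study tables
#'
#' Checks schemas, value domains (locality, cadre), non-negativity and
#' integrality of counts, referential integrity between tables, and — when
#' an activities table is supplied — completeness of the 99-activity
#' guaranteed package.
#'
#' @param study An `hrgap_study` (or plain list with the same elements).
#' @return Data frame of violations with columns `file`, `row`, `column`,
#'   `message`; zero rows when the study is valid.  The attribute
#'   `activity_total` carries the distinct-activity count when an activities
#'   table is present.
#' @export
validate_study <- function(study) {
  v <- list(no_violations())
  fac <- study$facilities; pop <- study$population; tim <- study$times
  act <- study$activities

  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      violation(file, NA, paste(miss, collapse = ","), "missing column(s)")
    else no_violations()
  }
  v[[length(v) + 1L]] <- need(fac, c("facility_id", "locality", unname(HEADCOUNT_COLS)),
                              "facilities.csv")
  v[[length(v) + 1L]] <- need(pop, c("facility_id", "age_group", "n"), "population.csv")
  v[[length(v) + 1L]] <- need(tim, c("facility_id", "age_group", "cadre",
                                     "minutes_used", "minutes_required"), "times.csv")
  if (nrow(do.call(rbind, v))) return(do.call(rbind, v))

  bad_loc <- which(!fac$locality %in% c("urban", "rural"))
  for (i in bad_loc)
    v[[length(v) + 1L]] <- violation("facilities.csv", i, "locality",
                                     sprintf("unknown locality '%s'", fac$locality[i]))
  if (anyDuplicated(fac$facility_id))
    v[[length(v) + 1L]] <- violation("facilities.csv", NA, "facility_id",
                                     "duplicate facility_id")
  for (col in unname(HEADCOUNT_COLS)) {
    x <- fac[[col]]
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    for (i in bad)
      v[[length(v) + 1L]] <- violation("facilities.csv", i, col,
                                       "headcount must be a non-negative integer")
  }

  bad_n <- which(is.na(pop$n) | pop$n < 0 | pop$n != floor(pop$n))
  for (i in bad_n)
    v[[length(v) + 1L]] <- violation("population.csv", i, "n",
                                     "population must be a non-negative integer")
  orphan <- which(!pop$facility_id %in% fac$facility_id)
  for (i in orphan)
    v[[length(v) + 1L]] <- violation("population.csv", i, "facility_id",
                                     sprintf("unknown facility '%s'", pop$facility_id[i]))

  bad_cadre <- which(!tim$cadre %in% CADRES)
  for (i in bad_cadre)
    v[[length(v) + 1L]] <- violation("times.csv", i, "cadre",
                                     sprintf("unknown cadre '%s'", tim$cadre[i]))
  for (col in c("minutes_used", "minutes_required")) {
    bad <- which(is.na(tim[[col]]) | tim[[col]] < 0)
    for (i in bad)
      v[[length(v) + 1L]] <- violation("times.csv", i, col,
                                       "minutes must be non-negative")
  }
  orphan <- which(!tim$facility_id %in% fac$facility_id)
  for (i in orphan)
    v[[length(v) + 1L]] <- violation("times.csv", i, "facility_id",
                                     sprintf("unknown facility '%s'", tim$facility_id[i]))
  # every timed facility x age group needs a population entry
  pop_key <- paste(pop$facility_id, pop$age_group)
  tim_key <- paste(tim$facility_id, tim$age_group)
  miss <- which(!tim_key %in% pop_key & tim$facility_id %in% fac$facility_id)
  for (i in unique(miss))
    v[[length(v) + 1L]] <- violation("times.csv", i, "age_group",
                                     sprintf("no population entry for facility '%s', age group '%s'",
                                             tim$facility_id[i], tim$age_group[i]))

  activity_total <- NA_integer_
  if (!is.null(act)) {
    v[[length(v) + 1L]] <- need(act, c("activity_id", "age_group", "cadre",
                                       "minutes_used", "minutes_required"),
                                "activities.csv")
    if (all(c("activity_id", "age_group", "cadre") %in% names(act))) {
      dup <- which(duplicated(act[c("age_group", "activity_id")]))
      for (i in dup)
        v[[length(v) + 1L]] <- violation("activities.csv", i, "activity_id",
                                         "duplicate activity within age group")
      bad <- which(!act$cadre %in% CADRES)
      for (i in bad)
        v[[length(v) + 1L]] <- violation("activities.csv", i, "cadre",
                                         sprintf("unknown cadre '%s'", act$cadre[i]))
      activity_total <- nrow(unique(act[c("age_group", "activity_id")]))
      if (activity_total != 99L)
        v[[length(v) + 1L]] <- violation("activities.csv", NA, "activity_id",
                                         sprintf("guaranteed package has 99 activities, found %d",
                                                 activity_total))
    }
  }

  out <- do.call(rbind, v)
  rownames(out) <- NULL
  attr(out, "activity_total") <- activity_total
  out
}
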