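#' Configuration for the synthetic-study generator
#'
#' Encodes the stated world the generator emulates: 20 facilities (12 urban,
#' 8 rural) in 10 states, 10 age groups whose activity counts sum to 99,
#' right-skewed (gamma) per-person service minutes calibrated so that each
#' group x cadre cell has its published median, time required inflated over
#' time used by the published ratios, headcounts calibrated to the published
#' facility columns, and 268 527 attended individuals split 87/13 between
#' urban and rural facilities.
#'
#' @param n_urban,n_rural Facility counts per locality (defaults 12 and 8).
#' @param group_times Data frame with columns `age_group`, `n_activities`,
#'   `population_share`, and per-cadre median minutes `tu_physician`,
#'   `tu_nurse`, `tu_hp`, `tr_physician`, `tr_nurse`, `tr_hp`.  Defaults to
#'   the published age-group table.
#' @param time_shape Gamma shape of the multiplicative service-time noise
#'   (default 2.5, comfortably above the 1.33 median-safety threshold).
#' @param tr_noise_shape Shape of the mean-1 gamma noise multiplying the
#'   required-over-used inflation factor (default 10, i.e. ~32% CV;
#'   `Inf` disables the noise entirely).
#' @param total_population Total attended individuals (default 268527).
#' @param urban_share Share of attended individuals in urban facilities
#'   (default 0.87).
#' @param concentration Symmetric Dirichlet concentration for allocating a
#'   locality's population across its facilities (default 2; smaller values
#'   give more unequal facilities).
#' @param headcount_pools Named list of empirical sampling pools
#'   (`physician_urban`, `physician_rural`, `hp_urban`, `hp_rural`).
#'   Defaults to the published per-facility counts, including the mostly-zero
#'   health-promoter columns.
#' @param nurse_nbinom Negative-binomial parameters for nurse headcounts per
#'   locality (list of `list(mu, size)`); the published tables print only
#'   stratum totals and medians for nurses, so these are calibrated to the
#'   urban total of 184 nurses (median 14.5) and rural total of 32 (median 1).
#' @param include_activities Also emit a study-level per-activity table whose
#'   group x cadre sums equal the target medians (default TRUE).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_urban = 12L,
                             n_rural = 8L,
                             group_times = NULL,
                             time_shape = 2.5,
                             tr_noise_shape = 10,
                             total_population = 268527L,
                             urban_share = 0.87,
                             concentration = 2,
                             headcount_pools = NULL,
                             nurse_nbinom = NULL,
                             include_activities = TRUE) {
  if (is.null(group_times)) group_times <- default_group_times()
  if (is.null(headcount_pools)) {
    fte <- reference_tables()$facility_fte
    headcount_pools <- list(
      physician_urban = as.integer(fte$phys_available[fte$locality == "urban"]),
      physician_rural = as.integer(fte$phys_available[fte$locality == "rural"]),
      hp_urban = as.integer(fte$hp_available[fte$locality == "urban"]),
      hp_rural = rep(0L, 8L)
    )
  }
  if (is.null(nurse_nbinom)) {
    nurse_nbinom <- list(urban = list(mu = 184 / 12, size = 25),
                         rural = list(mu = 32 / 8, size = 0.7))
  }
  need <- c("age_group", "n_activities", "population_share",
            "tu_physician", "tu_nurse", "tu_hp",
            "tr_physician", "tr_nurse", "tr_hp")
  miss <- setdiff(need, names(group_times))
  if (length(miss))
    stop("generator_config: group_times missing column(s): ",
         paste(miss, collapse = ", "))
  tu_cols <- c("tu_physician", "tu_nurse", "tu_hp")
  if (any(as.matrix(group_times[tu_cols]) < 0))
    stop("generator_config: negative target minutes")
  if (all(as.matrix(group_times[tu_cols]) == 0))
    stop("generator_config: all target minutes are zero")
  if (!(n_urban + n_rural >= 2L))
    stop("generator_config: need at least 2 facilities")
  if (time_shape <= 0 || tr_noise_shape <= 0 || concentration <= 0)
    stop("generator_config: shape and concentration parameters must be positive")
  if (urban_share <= 0 || urban_share >= 1)
    stop("generator_config: urban_share must lie in (0, 1)")
  if (total_population <= 0)
    stop("generator_config: total_population must be positive")
  if (abs(sum(group_times$population_share) - 1) > 1e-6)
    stop("generator_config: population shares must sum to 1")
  structure(
    list(n_urban = as.integer(n_urban), n_rural = as.integer(n_rural),
         group_times = group_times, time_shape = time_shape,
         tr_noise_shape = tr_noise_shape,
         total_population = as.integer(total_population),
         urban_share = urban_share, concentration = concentration,
         headcount_pools = headcount_pools, nurse_nbinom = nurse_nbinom,
         include_activities = isTRUE(include_activities)),
    class = "generator_config"
  )
}

# Target medians and shares for the 10 canonical age groups.
default_group_times <- function() {
  ag <- reference_age_groups()
  data.frame(
    age_group = ag$age_group,
    n_activities = ag$n_activities,
    population_share = ag$population / sum(ag$population),
    tu_physician = ag$tu_physician, tu_nurse = ag$tu_nurse, tu_hp = ag$tu_hp,
    tr_physician = ag$tr_physician, tr_nurse = ag$tr_nurse, tr_hp = ag$tr_hp,
    stringsAsFactors = FALSE
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic-study generator: %d urban + %d rural facilities\n",
              x$n_urban, x$n_rural))
  cat(sprintf("  attended population : %d (urban share %.2f)\n",
              x$total_population, x$urban_share))
  cat(sprintf("  age groups          : %d (activities total %d)\n",
              nrow(x$group_times), sum(x$group_times$n_activities)))
  cat(sprintf("  time noise shape    : %.2f\n", x$time_shape))
  invisible(x)
}

# Deterministic 32-bit sub-seed per facility so per-facility draws stay
# stable when the number of facilities changes.
facility_seed <- function(seed, locality, index, stage = 0L) {
  base <- if (locality == "urban") 100000L else 200000L
  (as.integer(seed) %% 1000003L) * 1009L + base + index * 7L + stage
}

mexican_states <- c("Morelos", "Ciudad de Mexico", "Hidalgo", "Queretaro",
                    "Guerrero", "Baja California", "Jalisco", "Campeche",
                    "Zacatecas", "Estado de Mexico")

#' Generate a synthetic facility study
#'
#' Draws a complete study — facilities, attended populations, and per-person
#' service times — with the statistical structure the pipeline assumes.  Per
#' group x cadre, time used is the target median multiplied by gamma noise
#' with median 1 (so the cell's median equals its target); time required is
#' time used times the published required/used inflation ratio times mean-1
#' gamma noise.  Populations are split urban/rural by `urban_share`, across
#' facilities by a symmetric Dirichlet allocation, and across age groups
#' multinomially by the published shares.  Fully reproducible from `seed`,
#' with per-facility sub-streams.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed governing every draw.
#' @return An [hrgap_study()] with attributes `config` and `seed`.
#' @examples
#' study <- generate_study(generator_config(), seed = 1)
#' study
#' @export
generate_study <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  gt <- config$group_times
  ng <- nrow(gt)
  localities <- c(rep("urban", config$n_urban), rep("rural", config$n_rural))
  index_within <- c(seq_len(config$n_urban), seq_len(config$n_rural))
  nf <- length(localities)
  ids <- ifelse(localities == "urban",
                sprintf("U%02d", index_within),
                sprintf("R%02d", index_within))

  tu_target <- as.matrix(gt[c("tu_physician", "tu_nurse", "tu_hp")])
  tr_target <- as.matrix(gt[c("tr_physician", "tr_nurse", "tr_hp")])
  med1 <- qgamma(0.5, shape = config$time_shape)  # divisor making median 1

  weights <- numeric(nf)
  fac_rows <- vector("list", nf)
  time_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    set.seed(facility_seed(seed, localities[f], index_within[f], 0L))
    weights[f] <- rgamma(1, shape = config$concentration, rate = 1)
    pool_p <- config$headcount_pools[[paste0("physician_", localities[f])]]
    pool_h <- config$headcount_pools[[paste0("hp_", localities[f])]]
    nn <- config$nurse_nbinom[[localities[f]]]
    hc_p <- pool_p[sample.int(length(pool_p), 1L)]
    hc_n <- rnbinom(1, size = nn$size, mu = nn$mu)
    hc_h <- pool_h[sample.int(length(pool_h), 1L)]

    noise_tu <- matrix(rgamma(ng * 3L, shape = config$time_shape) / med1,
                       nrow = ng)
    noise_tr <- if (is.infinite(config$tr_noise_shape)) {
      matrix(1, nrow = ng, ncol = 3L)  # noiseless limit of mean-1 gamma
    } else {
      matrix(rgamma(ng * 3L, shape = config$tr_noise_shape,
                    rate = config$tr_noise_shape), nrow = ng)
    }
    tu <- tu_target * noise_tu
    inflation <- ifelse(tu_target > 0, tr_target / pmax(tu_target, 1e-12), 0)
    tr <- ifelse(tu_target > 0, tu * inflation * noise_tr,
                 tr_target * noise_tu * noise_tr)

    fac_rows[[f]] <- data.frame(
      facility_id = ids[f],
      state = mexican_states[(f - 1L) %% length(mexican_states) + 1L],
      locality = localities[f],
      headcount_physician = hc_p, headcount_nurse = hc_n,
      headcount_hp = hc_h, stringsAsFactors = FALSE
    )
    time_rows[[f]] <- data.frame(
      facility_id = ids[f],
      age_group = rep(gt$age_group, times = 3L),
      cadre = rep(CADRES, each = ng),
      minutes_used = as.numeric(tu),
      minutes_required = as.numeric(tr),
      stringsAsFactors = FALSE
    )
  }

  # population: locality totals, Dirichlet-like facility split, then
  # multinomial age-group split inside each facility sub-stream (stage 1)
  urban_total <- round(config$total_population * config$urban_share)
  loc_total <- c(urban = urban_total,
                 rural = config$total_population - urban_total)
  fac_pop <- numeric(nf)
  for (l in c("urban", "rural")) {
    sel <- localities == l
    if (!any(sel)) next
    w <- weights[sel] / sum(weights[sel])
    fac_pop[sel] <- largest_remainder(loc_total[[l]] * w)
  }
  pop_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    set.seed(facility_seed(seed, localities[f], index_within[f], 1L))
    split <- as.numeric(rmultinom(1, size = fac_pop[f],
                                  prob = gt$population_share))
    pop_rows[[f]] <- data.frame(
      facility_id = ids[f], age_group = gt$age_group, n = split,
      stringsAsFactors = FALSE
    )
  }

  activities <- if (config$include_activities) make_activities(gt) else NULL
  study <- hrgap_study(
    facilities = do.call(rbind, fac_rows),
    population = do.call(rbind, pop_rows),
    times = do.call(rbind, time_rows),
    activities = activities,
    check = FALSE
  )
  attr(study, "config") <- config
  attr(study, "seed") <- as.integer(seed)
  study
}

# Integer allocation preserving the exact total (largest remainder method).
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x) - sum(fl)))
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  fl
}

# Study-level per-activity table: each group's activities are dealt
# round-robin to the cadres with positive target minutes and each cadre's
# group minutes split evenly among its activities, so the reducer recovers
# the group x cadre targets exactly.
make_activities <- function(gt) {
  rows <- list()
  for (g in seq_len(nrow(gt))) {
    tu <- c(gt$tu_physician[g], gt$tu_nurse[g], gt$tu_hp[g])
    tr <- c(gt$tr_physician[g], gt$tr_nurse[g], gt$tr_hp[g])
    active <- which(tu > 0 | tr > 0)
    n_act <- gt$n_activities[g]
    cadre_of <- active[(seq_len(n_act) - 1L) %% length(active) + 1L]
    for (cidx in active) {
      acts <- which(cadre_of == cidx)
      if (!length(acts)) next
      rows[[length(rows) + 1L]] <- data.frame(
        activity_id = sprintf("%s_a%02d", gt$age_group[g], acts),
        age_group = gt$age_group[g],
        cadre = CADRES[cidx],
        minutes_used = tu[cidx] / length(acts),
        minutes_required = tr[cidx] / length(acts),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Degenerate studies with known truth
#'
#' Small deterministic fixtures for pipeline testing:
#'
#' * `"no_gap"` — ideal supply exactly equals available supply at every
#'   facility; every gap is zero and the paired tests are skipped.
#' * `"all_gap"` — every facility is short in every cadre (ideal = 10x
#'   available from time used, 15x from time required); the Wilcoxon test
#'   must reject.
#' * `"zero_promoters"` — health-promoter headcount is zero everywhere while
#'   demand for promoter time is positive: available median 0, negative gap.
#'
#' @param kind One of `"no_gap"`, `"all_gap"`, `"zero_promoters"`.
#' @param n_facilities Number of facilities (default 12).
#' @return An [hrgap_study()].
#' @export
degenerate_study <- function(kind = c("no_gap", "all_gap", "zero_promoters"),
                             n_facilities = 12L) {
  kind <- match.arg(kind)
  n <- as.integer(n_facilities)
  stopifnot(n >= 2L)
  ids <- sprintf("F%02d", seq_len(n))
  localities <- rep(c("urban", "rural"), length.out = n)
  hc <- seq_len(n)  # physician headcounts 1..n
  pop <- 1200L

  # per-person annual minutes giving Is = As exactly for the no_gap case:
  # Is = minutes * pop / 60 = 60*h*1200/60 = 1200*h = As (h headcount)
  base_minutes <- 60 * hc
  mult_tu <- switch(kind, no_gap = 1, all_gap = 10, zero_promoters = 1)
  mult_tr <- switch(kind, no_gap = 1, all_gap = 15, zero_promoters = 1)

  hp_minutes_used <- if (kind == "zero_promoters") 30 else 0
  hp_minutes_required <- if (kind == "zero_promoters") 45 else 0

  facilities <- data.frame(
    facility_id = ids, state = mexican_states[(seq_len(n) - 1L) %% 10L + 1L],
    locality = localities,
    headcount_physician = hc, headcount_nurse = 0L, headcount_hp = 0L,
    stringsAsFactors = FALSE
  )
  population <- data.frame(facility_id = ids, age_group = "adults",
                           n = rep(pop, n), stringsAsFactors = FALSE)
  times <- rbind(
    data.frame(facility_id = ids, age_group = "adults", cadre = "physician",
               minutes_used = base_minutes * mult_tu,
               minutes_required = base_minutes * mult_tr,
               stringsAsFactors = FALSE),
    data.frame(facility_id = ids, age_group = "adults", cadre = "nurse",
               minutes_used = 0, minutes_required = 0,
               stringsAsFactors = FALSE),
    data.frame(facility_id = ids, age_group = "adults",
               cadre = "health_promoter",
               minutes_used = hp_minutes_used,
               minutes_required = hp_minutes_required,
               stringsAsFactors = FALSE)
  )
  hrgap_study(facilities, population, times, check = FALSE)
}
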