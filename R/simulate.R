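#' Build a simulation scenario
#'
#' The simulator emulates a two-station visible-migration count along a
#' coastal corridor: flocks cross a transect at a date drawn from a Gaussian
#' passage-date law, at a time of day drawn from a unimodal diurnal law (with
#' an optional early-morning component for harriers), at a continuous lateral
#' position (km from the coast) drawn per species. Stations sit at fixed
#' positions along the corridor; the nearer station records the flock (within
#' its detection range), assigning the distance zone implied by the lateral
#' offset. Flocks whose zone pair with the other station lies in the overlap
#' set may be double-recorded with probability \code{p_dup}. Identification
#' can fail with a probability that grows with viewing distance, in which
#' case the record carries an ancestor group code; crucially the failure law
#' depends on the group and the distance but not on the species, which is the
#' exchangeability assumption behind proportional reallocation. Entry times
#' get a recording-latency jitter (five minutes for harriers/falcons/rollers/
#' doves, ten for the rest).
#'
#' @param species tibble with one row per simulated species: columns
#'   \code{species}, \code{season_total} (individuals), \code{peak}
#'   (Date), \code{spread_days}, \code{flock_mean}, \code{lateral_mean_km},
#'   \code{lateral_sd_km}, \code{early_morning_frac}, \code{juv_frac},
#'   \code{ageing_prob}.
#' @param year season year.
#' @param uid_rates named per-group base probability that a pool-member bird
#'   is recorded as that group.
#' @param uid_distance if TRUE, identification failure scales with distance
#'   from the recording station.
#' @param p_dup probability that a flock visible from both stations is
#'   recorded by both.
#' @param detect_prob per-record detection probability within range.
#' @param detect_range_km named c(small, large) detection range.
#' @param station_km positions of stations 1 and 2 along the corridor.
#' @param age_sample_prob probability that a flock of an age-protocol species
#'   passing W1..E1 is age-sampled (emitting e.g. HB_JUV/HB_NONJUV records).
#' @param season_start,season_end month-day strings bounding the season.
#' @param em_window month-day strings bounding the early-morning extension.
#' @return an object of class \code{sim_scenario}.
#' @export
sim_scenario <- function(species,
                         year = 2017L,
                         uid_rates = c(Pernis_SPEC = 0.02,
                                       Buzzard_SPEC = 0.04,
                                       MediumRaptor = 0.03,
                                       MonPalHen = 0.10,
                                       Harrier_SPEC = 0.03,
                                       LargeEAGLE = 0.05,
                                       Raptor_SPEC = 0.01),
                         uid_distance = TRUE,
                         p_dup = 0.1,
                         detect_prob = 1,
                         detect_range_km = c(small = 3, large = 5),
                         station_km = c(2.4, 6.4),
                         age_sample_prob = 0.25,
                         season_start = "08-17", season_end = "10-16",
                         em_window = c("08-27", "09-27")) {
  stopifnot(all(uid_rates >= 0 & uid_rates <= 1), p_dup >= 0, p_dup <= 1,
            detect_prob >= 0, detect_prob <= 1,
            all(species$season_total >= 0))
  structure(list(
    species = species, year = year, uid_rates = uid_rates,
    uid_distance = uid_distance, p_dup = p_dup, detect_prob = detect_prob,
    detect_range_km = detect_range_km, station_km = station_km,
    age_sample_prob = age_sample_prob,
    season_start = as.Date(paste0(year, "-", season_start)),
    season_end = as.Date(paste0(year, "-", season_end)),
    em_start = as.Date(paste0(year, "-", em_window[1])),
    em_end = as.Date(paste0(year, "-", em_window[2])),
    std_start_min = 420, std_end_min = 1020, em_start_min = 360,
    midday_mean = 720, midday_sd = 130
  ), class = "sim_scenario")
}

#' Default five-species scenario
#'
#' Spans the mechanism space: a mass soaring species with a separate age
#' protocol (HB-like), a late-season soarer (Steppe-Buzzard-like), a scarce
#' ringtail harrier (Pallid-like), an early-morning flier (Marsh-harrier-
#' like), and a large eagle (Lesser-Spotted-like).
#' @param scale multiplier on season totals (smaller = faster runs).
#' @param ... passed to \code{\link{sim_scenario}}.
#' @return a \code{sim_scenario}.
#' @export
default_scenario <- function(scale = 1, ...) {
  year <- 2017L
  sp <- tibble(
    species = c("HB", "StepBuz", "Pal", "Mar", "LesserSE"),
    season_total = round(scale * c(20000, 6000, 600, 2500, 1500)),
    peak = as.Date(paste0(year, c("-08-28", "-10-01", "-09-10",
                                  "-09-05", "-09-25"))),
    spread_days = c(5, 7, 8, 10, 6),
    flock_mean = c(20, 10, 1.2, 1.5, 3),
    lateral_mean_km = c(3.5, 5.0, 3.0, 2.5, 4.5),
    lateral_sd_km = c(2.0, 2.5, 1.8, 1.5, 2.0),
    early_morning_frac = c(0, 0, 0.15, 0.25, 0),
    juv_frac = c(0.35, 0.3, 0.4, 0.35, 0.3),
    ageing_prob = c(0, 0, 0.85, 0.6, 0.7)
  )
  sim_scenario(sp, year = year, ...)
}

#' Misidentification-only recovery scenario
#'
#' All species share one tight coastal lateral law (so effectively a single
#' station records everything and double counting is impossible), detection
#' is certain, duplication is off, and identification failure is on. Under
#' these conditions the proportional reallocation of group records should
#' recover true species totals without bias.
#' @param birds_per_species season total per species.
#' @param ... passed to \code{\link{sim_scenario}}.
#' @return a \code{sim_scenario}.
#' @export
recovery_scenario <- function(birds_per_species = 10000, ...) {
  year <- 2017L
  sp <- tibble(
    species = c("HB", "StepBuz", "Pal", "Mar", "LesserSE"),
    season_total = rep(birds_per_species, 5),
    peak = as.Date(paste0(year, c("-08-28", "-10-01", "-09-10",
                                  "-09-05", "-09-25"))),
    spread_days = c(5, 7, 8, 10, 6),
    flock_mean = rep(5, 5),
    lateral_mean_km = rep(1.5, 5),
    lateral_sd_km = rep(0.5, 5),
    early_morning_frac = rep(0, 5),
    juv_frac = c(0.35, 0.3, 0.4, 0.35, 0.3),
    ageing_prob = c(0, 0, 0.9, 0.9, 0.9)
  )
  sim_scenario(sp, year = year, p_dup = 0, detect_prob = 1, ...)
}

#' Duplication-only scenario
#'
#' A single solitary-flying species whose whole passage crosses inside the
#' two-station overlap band, with identification always succeeding, so every
#' removal decision is attributable against the planted ground truth.
#' @param n_flocks flocks (= individuals; flock size is one).
#' @param p_dup double-recording probability in the overlap band.
#' @param ... passed to \code{\link{sim_scenario}}.
#' @return a \code{sim_scenario}.
#' @export
duplication_scenario <- function(n_flocks = 1000, p_dup = 0.2, ...) {
  year <- 2017L
  sp <- tibble(
    species = "Pal",
    season_total = n_flocks,
    peak = as.Date(paste0(year, "-09-10")),
    spread_days = 10,
    flock_mean = 1,
    lateral_mean_km = 4.4,   # mid-way between the stations
    lateral_sd_km = 0.45,
    early_morning_frac = 0,
    juv_frac = 0.4,
    ageing_prob = 1
  )
  sim_scenario(sp, year = year, p_dup = p_dup, detect_prob = 1,
               uid_rates = c(Raptor_SPEC = 0), ...)
}

# lateral offset (km, signed, east positive) -> distance zone code
zone_from_offset <- function(o) {
  side <- ifelse(o < 0, "W", "E")
  a <- abs(o)
  mag <- findInterval(a, c(0.25, 1, 2, 4)) # 0=O band
  mag[side == "W" & mag == 4] <- 3         # W4 does not exist
  ifelse(mag == 0, "O", paste0(side, mag))
}

# species recorded as which code, given distance from recording station.
# failure probability is group- and distance-specific, never species-specific.
draw_recorded_code <- function(species, dist_km, scenario, hierarchy) {
  n <- length(species)
  out <- species
  fd <- if (scenario$uid_distance) pmin(1.5, 0.4 + dist_km / 2) else rep(1, n)
  for (sp in unique(species)) {
    idx <- which(species == sp)
    chain <- ancestors(sp, hierarchy)
    chain <- chain[chain %in% names(scenario$uid_rates)]
    if (length(chain) == 0) next
    w <- outer(fd[idx], scenario$uid_rates[chain]) # n_idx x n_chain
    w <- pmin(w, 1)
    # sequential thinning: try most specific group first
    u <- matrix(stats::runif(length(w)), nrow = length(idx))
    assigned <- rep(NA_character_, length(idx))
    for (j in seq_along(chain)) {
      hit <- is.na(assigned) & u[, j] < w[, j]
      assigned[hit] <- chain[j]
    }
    out[idx][!is.na(assigned)] <- assigned[!is.na(assigned)]
  }
  out
}

LATENCY_5MIN <- c("Mar", "Mon", "Pal", "Hen", "LesserKes", "CommonKes",
                  "RedFF", "EleonoraF", "Merlin", "Hobby", "LannerF",
                  "SakerF", "Peregrine", "Roller", "TurtleD", "WoodP",
                  "StockD")
AGE_PROTOCOL_SPECIES <- c("HB", "StepBuz", "BlackKite")

#' Simulate a season of two-station count records with ground truth
#'
#' @param scenario a \code{sim_scenario}.
#' @param seed integer seed; runs are reproducible given the seed.
#' @param config a \code{protocol_config} (overlap zones decide where
#'   double-recording is possible).
#' @param hierarchy an \code{id_hierarchy}.
#' @return list with \code{records} (count-record tibble in the standard
#'   schema, ids assigned in chronological order) and \code{truth} (one row
#'   per simulated flock: species, n, n_juv, date, crossing time, lateral
#'   position, recording station(s), recorded codes, record ids, filter of
#'   the primary record).
#' @export
simulate_season <- function(scenario, seed = 1L,
                            config = default_protocol(),
                            hierarchy = default_hierarchy()) {
  set.seed(seed)
  sp_tbl <- scenario$species
  all_rec <- list()
  all_truth <- list()
  flock_offset <- 0L

  for (i in seq_len(nrow(sp_tbl))) {
    s <- sp_tbl[i, ]
    if (s$season_total <= 0) next
    n_fl <- max(1L, round(s$season_total / s$flock_mean))
    size <- if (s$flock_mean <= 1) rep(1L, n_fl) else
      1L + stats::rgeom(n_fl, prob = 1 / s$flock_mean)
    # age-protocol species are aged per individual (a stream mixes classes);
    # other species are recorded per class, so a record is one class
    if (s$species %in% AGE_PROTOCOL_SPECIES) {
      n_juv <- stats::rbinom(n_fl, size, s$juv_frac)
    } else {
      n_juv <- size * (stats::runif(n_fl) < s$juv_frac)
    }

    date <- s$peak + round(stats::rnorm(n_fl, 0, s$spread_days))
    date <- pmin(pmax(date, scenario$season_start), scenario$season_end)

    em_ok <- s$early_morning_frac > 0 & date >= scenario$em_start &
      date <= scenario$em_end
    em <- em_ok & stats::runif(n_fl) < s$early_morning_frac
    tmin <- ifelse(
      em,
      stats::runif(n_fl, scenario$em_start_min, scenario$std_start_min),
      pmin(pmax(stats::rnorm(n_fl, scenario$midday_mean, scenario$midday_sd),
                scenario$std_start_min), scenario$std_end_min - 1)
    )

    x <- pmin(pmax(stats::rnorm(n_fl, s$lateral_mean_km, s$lateral_sd_km),
                   0.05), 11.95)
    d1 <- x - scenario$station_km[1]
    d2 <- x - scenario$station_km[2]
    primary <- ifelse(abs(d1) <= abs(d2), 1L, 2L)
    d_primary <- ifelse(primary == 1L, d1, d2)
    d_other <- ifelse(primary == 1L, d2, d1)

    cls <- size_class(s$species, config)
    in_range <- abs(d_primary) <= scenario$detect_range_km[[cls]]
    recorded <- in_range & stats::runif(n_fl) < scenario$detect_prob

    zone_primary <- zone_from_offset(d_primary)
    zone_other <- zone_from_offset(d_other)
    z1 <- ifelse(primary == 1L, zone_primary, zone_other)
    z2 <- ifelse(primary == 1L, zone_other, zone_primary)
    dup_possible <- recorded &
      abs(d_other) <= scenario$detect_range_km[[cls]] &
      zone_pair_overlaps(z1, z2, cls, config)
    dup <- dup_possible & stats::runif(n_fl) < scenario$p_dup

    latency <- if (s$species %in% LATENCY_5MIN) 5 else 10
    t_rec1 <- tmin + stats::runif(n_fl, 0, latency)
    t_rec2 <- tmin + stats::runif(n_fl, 0, latency)

    code1 <- draw_recorded_code(rep(s$species, n_fl), abs(d_primary),
                                scenario, hierarchy)
    code2 <- draw_recorded_code(rep(s$species, n_fl), abs(d_other),
                                scenario, hierarchy)

    is_protocol <- s$species %in% AGE_PROTOCOL_SPECIES
    flock_juv <- n_juv > 0 & n_juv == size # record-level class
    aged1 <- !is_protocol & stats::runif(n_fl) < s$ageing_prob
    aged2 <- !is_protocol & stats::runif(n_fl) < s$ageing_prob / 2
    age1 <- ifelse(aged1, ifelse(flock_juv, "juv", "ad"), NA_character_)
    age2 <- ifelse(aged2, ifelse(flock_juv, "juv", "ad"), NA_character_)
    # age only meaningful on codes at/below the species' ringtail level;
    # groups can carry age too (age is often easier than species)
    age1[is_group(code1, hierarchy) &
           !code1 %in% c("MonPalHen", "LargeEAGLE")] <- NA
    age2[is_group(code2, hierarchy) &
           !code2 %in% c("MonPalHen", "LargeEAGLE")] <- NA

    flock_id <- flock_offset + seq_len(n_fl)
    flock_offset <- flock_offset + n_fl

    rec_p <- tibble(
      flock_id = flock_id[recorded], role = "primary",
      date = date[recorded], time_min = t_rec1[recorded],
      species = code1[recorded], number = size[recorded],
      station = primary[recorded], location = zone_primary[recorded],
      age = age1[recorded]
    )
    rec_s <- tibble(
      flock_id = flock_id[dup], role = "secondary",
      date = date[dup], time_min = t_rec2[dup],
      species = code2[dup], number = size[dup],
      station = 3L - primary[dup], location = zone_other[dup],
      age = age2[dup]
    )
    recs <- dplyr::bind_rows(rec_p, rec_s)

    # dedicated age-protocol sampling for HB-like species, W1..E1 only
    if (is_protocol && s$ageing_prob >= 0) {
      sampled <- recorded & zone_primary %in% c("W1", "O", "E1") &
        stats::runif(n_fl) < scenario$age_sample_prob
      if (any(sampled)) {
        prefix <- c(HB = "HB", StepBuz = "SB", BlackKite = "BK")[[s$species]]
        aj <- tibble(
          flock_id = flock_id[sampled], role = "age_juv",
          date = date[sampled], time_min = t_rec1[sampled],
          species = paste0(prefix, "_JUV"), number = n_juv[sampled],
          station = primary[sampled], location = zone_primary[sampled],
          age = NA_character_
        )
        an <- tibble(
          flock_id = flock_id[sampled], role = "age_nonjuv",
          date = date[sampled], time_min = t_rec1[sampled],
          species = paste0(prefix, "_NONJUV"),
          number = (size - n_juv)[sampled],
          station = primary[sampled], location = zone_primary[sampled],
          age = NA_character_
        )
        recs <- dplyr::bind_rows(recs, aj[aj$number > 0, ],
                                 an[an$number > 0, ])
      }
    }

    all_rec[[i]] <- recs
    all_truth[[i]] <- tibble(
      flock_id = flock_id, species = s$species, n = size, n_juv = n_juv,
      date = date, crossing_min = tmin, x_km = x,
      primary_station = primary, recorded = recorded, dup_recorded = dup,
      code_primary = ifelse(recorded, code1, NA_character_),
      code_secondary = ifelse(dup, code2, NA_character_)
    )
  }

  recs <- dplyr::bind_rows(all_rec)
  truth <- dplyr::bind_rows(all_truth)
  if (nrow(recs) == 0) {
    return(list(records = empty_records(), truth = truth))
  }

  recs <- recs[order(recs$date, recs$time_min, recs$flock_id), ]
  recs$id <- seq_len(nrow(recs))
  filt <- record_filter(recs$date, recs$time_min, recs$species, scenario)

  records <- count_records(
    id = recs$id, date = recs$date,
    time = minutes_to_time(recs$time_min),
    species = recs$species, number = recs$number, north = 0L,
    station = recs$station, location = recs$location, age = recs$age,
    filter = filt
  )

  key_p <- recs$id[recs$role == "primary"]
  names(key_p) <- recs$flock_id[recs$role == "primary"]
  key_s <- recs$id[recs$role == "secondary"]
  names(key_s) <- recs$flock_id[recs$role == "secondary"]
  truth$record_id_primary <- unname(key_p[as.character(truth$flock_id)])
  truth$record_id_secondary <- unname(key_s[as.character(truth$flock_id)])
  truth$filter_primary <- records$filter[match(truth$record_id_primary,
                                               records$id)]
  list(records = records, truth = truth)
}

# standardized / early-morning / non-standardized flag from recorded time
record_filter <- function(date, time_min, species, scenario) {
  harrierish <- species %in% c("Mar", "Mon", "Pal", "Hen", "MonPalHen",
                               "Harrier_SPEC")
  in_season <- date >= scenario$season_start & date <= scenario$season_end
  std <- time_min >= scenario$std_start_min & time_min <= scenario$std_end_min
  em <- time_min >= scenario$em_start_min & time_min < scenario$std_start_min &
    harrierish & date >= scenario$em_start & date <= scenario$em_end
  ifelse(!in_season, 0L, ifelse(std, 1L, ifelse(em, 2L, 0L)))
}

#' Run the full pipeline over a simulated season and score recovery
#'
#' Simulates, validates, removes double counts, allocates unidentified
#' birds, and compares the result with the planted ground truth.
#'
#' @param scenario a \code{sim_scenario}.
#' @param seed integer seed.
#' @param config a \code{protocol_config}.
#' @param hierarchy an \code{id_hierarchy}.
#' @param filterset filter classes the totals are computed over.
#' @param stages pipeline stages to run between simulation and totals.
#' @return list with \code{species} (per-species tibble: true_total,
#'   recovered, rel_error), \code{dedup} (planted/removed/true-positive/
#'   false-positive individuals, sensitivity, specificity), \code{age}
#'   (per-species juvenile-total recovery where age data exist), plus the
#'   intermediate \code{records} and \code{truth}.
#' @export
evaluate_pipeline <- function(scenario, seed = 1L,
                              config = default_protocol(),
                              hierarchy = default_hierarchy(),
                              filterset = 1L,
                              stages = c("validate", "dedupe", "allocate")) {
  sim <- simulate_season(scenario, seed, config, hierarchy)
  records <- sim$records
  truth <- sim$truth

  if ("validate" %in% stages) {
    records <- integrity_pass(records, hierarchy, config)$records
  }
  dedup_report <- NULL
  if ("dedupe" %in% stages) {
    dd <- remove_double_counts(records, config, hierarchy)
    records <- dd$records
    dedup_report <- dd$report
  }
  daily <- estimate_daily_species_totals(records, config, hierarchy,
                                         filterset = filterset)
  est <- annual_totals(daily, variant = "allocated")

  eligible <- truth$recorded & truth$filter_primary %in% filterset
  true_tot <- stats::aggregate(n ~ species, data = truth[eligible, ],
                               FUN = sum)
  species_metrics <- tibble(
    species = true_tot$species,
    true_total = as.numeric(true_tot$n),
    recovered = est$total[match(true_tot$species, est$species)]
  )
  species_metrics$recovered[is.na(species_metrics$recovered)] <- 0
  species_metrics$rel_error <-
    (species_metrics$recovered - species_metrics$true_total) /
    species_metrics$true_total

  dedup <- NULL
  if (!is.null(dedup_report)) {
    planted_fl <- truth[truth$dup_recorded, ]
    planted_ind <- sum(planted_fl$n)
    adj <- dedup_report$adjustments
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    truth_pairs <- pair_key(planted_fl$record_id_primary,
                            planted_fl$record_id_secondary)
    dup_rec_ids <- c(planted_fl$record_id_primary,
                     planted_fl$record_id_secondary)
    tp_strict <- adj$quantity[pair_key(adj$kept_id, adj$reduced_id) %in%
                                truth_pairs]
    # a planted duplicate counts as removed when the flock's own excess was
    # taken out: per flock, the reduction applied to its two records capped
    # at its size (whichever record the matcher paired it with)
    red_by_id <- tapply(adj$quantity, adj$reduced_id, sum)
    red_q <- function(ids) {
      q <- red_by_id[as.character(ids)]
      q[is.na(q)] <- 0
      unname(q)
    }
    corrected <- pmin(red_q(planted_fl$record_id_primary) +
                        red_q(planted_fl$record_id_secondary),
                      planted_fl$n)
    tp_loose <- corrected
    dedup <- list(
      planted_flocks = nrow(planted_fl),
      planted_individuals = planted_ind,
      removed_individuals = dedup_report$n_individuals_removed,
      tp_individuals = sum(tp_loose),
      tp_exact_pairs = sum(tp_strict),
      fp_individuals = dedup_report$n_individuals_removed - sum(tp_loose),
      sensitivity = if (planted_ind > 0) sum(tp_loose) / planted_ind else NA,
      n_flocks_in_band = sum(truth$recorded &
                               !is.na(truth$code_primary) &
                               dup_band(truth, scenario, config, hierarchy))
    )
  }

  age <- age_recovery(records, truth, daily, eligible, hierarchy, scenario)

  list(species = species_metrics, dedup = dedup, age = age,
       records = records, truth = truth, daily = daily)
}

# flocks whose zone pair lies inside the overlap set for their size class
dup_band <- function(truth, scenario, config, hierarchy) {
  d1 <- truth$x_km - scenario$station_km[1]
  d2 <- truth$x_km - scenario$station_km[2]
  cls <- size_class(truth$species, config)
  z1 <- zone_from_offset(d1)
  z2 <- zone_from_offset(d2)
  in_range <- abs(ifelse(truth$primary_station == 1L, d2, d1)) <=
    scenario$detect_range_km[cls]
  ov <- logical(nrow(truth))
  for (cl in unique(cls)) {
    idx <- cls == cl
    ov[idx] <- zone_pair_overlaps(z1[idx], z2[idx], cl, config)
  }
  ov & in_range
}

age_recovery <- function(records, truth, daily, eligible, hierarchy,
                         scenario) {
  out <- list()
  for (sp in unique(truth$species)) {
    props <- age_proportions(records, sp, hierarchy = hierarchy)
    if (nrow(props) == 0 || !"juv" %in% props$age) next
    act <- tryCatch(
      age_class_totals(daily, props, species = sp),
      error = function(e) NULL)
    if (is.null(act)) next
    est_juv <- sum(act$total[act$age == "juv"])
    true_juv <- sum(truth$n_juv[eligible & truth$species == sp])
    out[[sp]] <- tibble(species = sp, true_juv = true_juv,
                        est_juv = est_juv,
                        rel_error = (est_juv - true_juv) /
                          max(true_juv, 1))
  }
  if (length(out)) dplyr::bind_rows(out) else NULL
}
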