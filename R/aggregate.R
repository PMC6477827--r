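#' Keep records from the given filter classes
#'
#' filter 0 = non-standardized, 1 = standardized, 2 = standardized early
#' morning count. Most analyses should use \code{c(1)}; harrier analyses that
#' include the early-morning extension use \code{c(1, 2)}.
#'
#' @param records count-record tibble.
#' @param filter_values subset of c(0, 1, 2).
#' @return the filtered records.
#' @export
select_standardized <- function(records, filter_values = 1L) {
  records[records$filter %in% filter_values, ]
}

# accept either a daily_totals object or a plain (date, species, total) table
daily_value_table <- function(daily, variant = c("allocated", "raw")) {
  variant <- match.arg(variant)
  if (inherits(daily, "daily_totals") || all(c("raw", "allocated") %in%
                                             names(daily))) {
    tibble(date = daily$date, species = daily$species,
           total = daily[[variant]])
  } else {
    stopifnot(all(c("date", "species", "total") %in% names(daily)))
    tibble(date = daily$date, species = daily$species, total = daily$total)
  }
}

#' Annual species totals from a daily-totals table
#'
#' @param daily a \code{daily_totals} object (or a tibble with date, species,
#'   total columns).
#' @param year calendar year (integer); NULL sums everything.
#' @param variant "allocated" (default) or "raw".
#' @return tibble with species, total.
#' @export
annual_totals <- function(daily, year = NULL, variant = "allocated") {
  d <- daily_value_table(daily, variant)
  if (!is.null(year)) {
    d <- d[as.integer(format(d$date, "%Y")) == year, ]
  }
  if (nrow(d) == 0) return(tibble(species = character(), total = numeric()))
  agg <- stats::aggregate(total ~ species, data = d, FUN = sum)
  as_tibble(agg[order(agg$species), ])
}

#' Passage-date quantile of a species
#'
#' The earliest date at which the cumulative season total reaches the given
#' fraction of the full season total. Day-resolution, no interpolation.
#'
#' @param daily daily totals (see \code{\link{annual_totals}}).
#' @param species a species code present in the table.
#' @param q fraction in (0, 1).
#' @param variant "allocated" (default) or "raw".
#' @return a Date.
#' @export
passage_quantile <- function(daily, species, q, variant = "allocated") {
  stopifnot(q > 0, q < 1)
  d <- daily_value_table(daily, variant)
  d <- d[d$species == species, ]
  d <- d[order(d$date), ]
  total <- sum(d$total)
  if (total <= 0) {
    stop("no passage recorded for ", species, call. = FALSE)
  }
  cum <- cumsum(d$total)
  d$date[which(cum >= q * total)[1]]
}

#' Standardized season window from phenology rules
#'
#' The count season is anchored on the earliest and latest priority species:
#' it opens a fixed number of days before an early-passage quantile of one
#' species and closes a fixed number of days after a late-passage quantile of
#' another (defaults: 3 days before the 1\% quantile of Montagu's Harrier to
#' 3 days after the 99\% quantile of Lesser Spotted Eagle).
#'
#' @param daily daily totals covering both rule species.
#' @param config a \code{protocol_config} carrying season_start_rule and
#'   season_end_rule.
#' @param variant "allocated" (default) or "raw".
#' @return list with \code{start}, \code{end} (Dates) and \code{basis}.
#' @export
season_window <- function(daily, config = default_protocol(),
                          variant = "allocated") {
  d <- daily_value_table(daily, variant)
  for (rule in list(config$season_start_rule, config$season_end_rule)) {
    if (!rule$species %in% d$species[d$total > 0]) {
      stop("season rule species missing from daily totals: ", rule$species,
           call. = FALSE)
    }
  }
  sr <- config$season_start_rule
  er <- config$season_end_rule
  start <- passage_quantile(daily, sr$species, sr$quantile, variant) +
    sr$offset
  end <- passage_quantile(daily, er$species, er$quantile, variant) +
    er$offset
  stopifnot(start <= end)
  list(start = start, end = end,
       basis = list(start = sr, end = er))
}

#' Daily age-class proportions of a species
#'
#' For species with a dedicated age protocol (European Honey-buzzard, Black
#' Kite, Steppe Buzzard) proportions come from the age-protocol codes only
#' (HB_JUV/HB_NONJUV, ...): regular records of these species are not an
#' age sample. For every other species, proportions come from regular
#' records that carry age information. Fractions are over individuals and
#' sum to one per date; dates without aged individuals are absent.
#'
#' @param records count-record tibble (post-dedup).
#' @param species a species code.
#' @param date optional single date; NULL returns all dates.
#' @param hierarchy an \code{id_hierarchy}.
#' @param filterset filter classes to include.
#' @return tibble with date, age (class label), n (aged individuals),
#'   fraction.
#' @export
age_proportions <- function(records, species, date = NULL,
                            hierarchy = default_hierarchy(),
                            filterset = c(1L, 2L)) {
  r <- records[records$filter %in% filterset, ]
  protocol_codes <- names(hierarchy$age_codes)[hierarchy$age_codes == species]
  if (length(protocol_codes)) {
    r <- r[r$species %in% protocol_codes, ]
    cls <- ifelse(grepl("_JUV$", r$species), "juv", "nonjuv")
  } else {
    r <- r[r$species == species & !is.na(r$age), ]
    cls <- r$age
  }
  if (!is.null(date)) r <- r[r$date == date, ]
  if (nrow(r) == 0) {
    return(tibble(date = as.Date(character()), age = character(),
                  n = numeric(), fraction = numeric()))
  }
  agg <- stats::aggregate(number ~ date + cls,
                          data = data.frame(date = r$date, cls = cls,
                                            number = r$number),
                          FUN = sum)
  day_tot <- stats::aggregate(number ~ date, data = agg, FUN = sum)
  frac <- agg$number / day_tot$number[match(agg$date, day_tot$date)]
  out <- tibble(date = agg$date, age = agg$cls, n = as.numeric(agg$number),
                fraction = frac)
  out[order(out$date, out$age), ]
}

#' Daily age-class totals from species totals and age proportions
#'
#' Multiplies each day's (allocated) species total by that day's age-class
#' fractions. Days with passage but no aged sample fall back to the
#' season-pooled proportions (individual-weighted) so class totals still sum
#' to the species total; such days are marked \code{fallback = TRUE}.
#'
#' @param daily daily totals for one species (see
#'   \code{\link{annual_totals}}); rows for other species are ignored if a
#'   \code{species} argument is given.
#' @param proportions tibble from \code{\link{age_proportions}}.
#' @param species optional species code to restrict \code{daily} to.
#' @param variant "allocated" (default) or "raw".
#' @return tibble with date, age, total, fallback.
#' @export
age_class_totals <- function(daily, proportions, species = NULL,
                             variant = "allocated") {
  d <- daily_value_table(daily, variant)
  if (!is.null(species)) d <- d[d$species == species, ]
  d <- d[d$total > 0, ]
  classes <- sort(unique(proportions$age))
  if (length(classes) == 0) {
    stop("no aged individuals in the proportions table", call. = FALSE)
  }
  pooled_n <- vapply(classes, function(a) {
    sum(proportions$n[proportions$age == a])
  }, numeric(1))
  pooled <- pooled_n / sum(pooled_n)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    p <- proportions[proportions$date == d$date[i], ]
    if (nrow(p)) {
      frac <- stats::setNames(rep(0, length(classes)), classes)
      frac[p$age] <- p$fraction
      fb <- FALSE
    } else {
      frac <- pooled
      fb <- TRUE
    }
    tibble(date = d$date[i], age = classes,
           total = d$total[i] * unname(frac), fallback = fb)
  })
  dplyr::bind_rows(rows)
}

#' Count as a percentage of the world population estimate
#'
#' Population estimates come as a (low, high) range; the count is expressed
#' against both ends, giving the (low\%, high\%) pair: dividing by the high
#' estimate gives the low percentage and vice versa. Nearest-integer
#' (half-up) rounding.
#'
#' @param count individuals counted.
#' @param pop_low,pop_high world population estimate range, both > 0,
#'   pop_low <= pop_high.
#' @return named numeric c(low, high) of integer percentages.
#' @export
#' @examples
#' world_population_percentage(499493, 280000, 420000)  # 119 178
world_population_percentage <- function(count, pop_low, pop_high) {
  if (pop_low <= 0 || pop_high <= 0) {
    stop("population estimates must be positive", call. = FALSE)
  }
  stopifnot(pop_low <= pop_high)
  c(low = round_half_up(100 * count / pop_high),
    high = round_half_up(100 * count / pop_low))
}

#' Additional percentage contributed by early-morning counts
#'
#' Relative gain of the season total when standardized early-morning records
#' (filter 2) are added to the standard total (filter 1), as an integer
#' percentage.
#'
#' @param total_with season total including early-morning counts.
#' @param total_standard season total from the standard window only.
#' @return integer percent, or NA (with a warning) when the standard total is
#'   zero.
#' @export
#' @examples
#' early_morning_addition(8458, 7296)  # 16
early_morning_addition <- function(total_with, total_standard) {
  if (total_standard == 0) {
    warning("standard total is zero; early-morning addition undefined")
    return(NA_real_)
  }
  round_half_up(100 * (total_with - total_standard) / total_standard)
}
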