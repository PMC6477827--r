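#' Daily raw totals per species and per morphological group
#'
#' Sums \code{number} per code and date over the selected filter classes,
#' splitting species-level codes from group-level codes. Age-protocol codes
#' (HB_JUV, ...) are sampling records, not counts, and are excluded from both
#' tables.
#'
#' @param records deduplicated count-record tibble.
#' @param filterset subset of c(0, 1, 2) to keep (default standardized only).
#' @param hierarchy an \code{id_hierarchy}.
#' @return list of two tibbles, \code{species} and \code{groups}, each with
#'   columns date, code, total.
#' @export
daily_raw_totals <- function(records, filterset = 1L,
                             hierarchy = default_hierarchy()) {
  r <- records[records$filter %in% filterset &
                 !records$species %in% names(hierarchy$age_codes), ]
  tot <- function(x) {
    if (nrow(x) == 0) {
      return(tibble(date = as.Date(character()), code = character(),
                    total = numeric()))
    }
    agg <- stats::aggregate(number ~ date + species, data = x, FUN = sum)
    tibble(date = agg$date, code = agg$species, total = as.numeric(agg$number))
  }
  grp <- is_group(r$species, hierarchy)
  list(species = tot(r[!grp, ]), groups = tot(r[grp, ]))
}

#' Allocate one day's group counts to species
#'
#' Groups are processed from most specific to most general (bottom-up in the
#' hierarchy). A group with N birds hands each pool species s the share
#' N * T_s / sum(T_pool), where T are the running species totals -- i.e.
#' totals already augmented by the more specific groups processed before.
#' Fractions are kept unrounded.
#'
#' When the whole pool has a zero running total, the fallback decides:
#' season-wide pool proportions (default, keeps conservation), equal split,
#' or skip (leave unallocated and report).
#'
#' @param date the date (bookkeeping only).
#' @param species_totals named numeric: identified daily totals per species.
#' @param group_totals named numeric: daily totals per group code.
#' @param hierarchy an \code{id_hierarchy}.
#' @param fallback one of "season_proportions", "skip", "equal_split".
#' @param season_pool_totals named numeric of season-wide identified species
#'   totals, used by the season_proportions fallback.
#' @param allocate_nonraptor_groups also allocate non-raptor groups such as
#'   Stork_SPEC (default TRUE).
#' @return list with \code{totals} (named numeric, allocated species totals)
#'   and \code{unallocated} (named numeric per group that could not be
#'   resolved).
#' @export
allocate_day <- function(date, species_totals, group_totals,
                         hierarchy = default_hierarchy(),
                         fallback = "season_proportions",
                         season_pool_totals = NULL,
                         allocate_nonraptor_groups = TRUE) {
  totals <- stats::setNames(rep(0, length(hierarchy$species)),
                            hierarchy$species)
  totals[names(species_totals)] <- species_totals
  groups <- names(group_totals)[group_totals > 0]
  if (!allocate_nonraptor_groups) {
    raptorish <- vapply(groups, function(g) {
      g == "Raptor_SPEC" || "Raptor_SPEC" %in% ancestors(g, hierarchy)
    }, logical(1))
    unalloc_nr <- group_totals[groups[!raptorish]]
    groups <- groups[raptorish]
  }
  depth <- vapply(groups, hierarchy_depth, numeric(1), hierarchy = hierarchy)
  groups <- groups[order(-depth, groups)]
  unallocated <- numeric()

  for (g in groups) {
    n_g <- group_totals[[g]]
    pool <- hierarchy$pools[[g]]
    w <- totals[pool]
    if (sum(w) <= 0) {
      w <- switch(fallback,
        season_proportions = {
          sw <- if (is.null(season_pool_totals)) numeric(length(pool)) else {
            out <- season_pool_totals[pool]
            out[is.na(out)] <- 0
            out
          }
          sw
        },
        equal_split = rep(1, length(pool)),
        skip = numeric(length(pool))
      )
    }
    if (sum(w) <= 0) {
      unallocated[g] <- n_g
      next
    }
    totals[pool] <- totals[pool] + n_g * w / sum(w)
  }
  if (!allocate_nonraptor_groups && length(unalloc_nr)) {
    unallocated <- c(unallocated, unalloc_nr[unalloc_nr > 0])
  }
  list(totals = totals, unallocated = unallocated)
}

#' Estimate daily species totals, with and without unidentified birds
#'
#' Computes per-date identified totals, then reallocates every morphological
#' group's count to its pool species by iterating the proportional rule up
#' the hierarchy (\code{\link{allocate_day}}). Returns both variants so the
#' contribution of unidentified birds stays visible.
#'
#' @param records deduplicated, validated count-record tibble.
#' @param config a \code{protocol_config} (fallback and toggles).
#' @param hierarchy an \code{id_hierarchy}.
#' @param filterset filter classes to include (default standardized, 1).
#' @return an object of class \code{daily_totals}: a tibble with columns
#'   date, species, raw (identified individuals) and allocated (identified +
#'   allocated share of group counts); attribute \code{unallocated} is a
#'   tibble of per-date group counts that could not be resolved.
#' @export
estimate_daily_species_totals <- function(records,
                                          config = default_protocol(),
                                          hierarchy = default_hierarchy(),
                                          filterset = 1L) {
  raw <- daily_raw_totals(records, filterset, hierarchy)
  dates <- sort(unique(c(raw$species$date, raw$groups$date)))
  season_pool <- if (nrow(raw$species)) {
    agg <- stats::aggregate(total ~ code, data = raw$species, FUN = sum)
    stats::setNames(agg$total, agg$code)
  } else numeric()

  rows <- vector("list", length(dates))
  unalloc <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    d <- dates[i]
    sp <- raw$species[raw$species$date == d, ]
    gr <- raw$groups[raw$groups$date == d, ]
    res <- allocate_day(
      d,
      stats::setNames(sp$total, sp$code),
      stats::setNames(gr$total, gr$code),
      hierarchy, fallback = config$empty_pool_fallback,
      season_pool_totals = season_pool,
      allocate_nonraptor_groups = config$allocate_nonraptor_groups
    )
    raw_day <- stats::setNames(rep(0, length(hierarchy$species)),
                               hierarchy$species)
    raw_day[sp$code] <- sp$total
    nz <- raw_day > 0 | res$totals > 0
    rows[[i]] <- tibble(date = d, species = names(res$totals)[nz],
                        raw = unname(raw_day[nz]),
                        allocated = unname(res$totals[nz]))
    if (length(res$unallocated)) {
      unalloc[[i]] <- tibble(date = d, group = names(res$unallocated),
                             count = unname(res$unallocated))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(date = as.Date(character()), species = character(),
           raw = numeric(), allocated = numeric())
  unalloc <- unalloc[!vapply(unalloc, is.null, logical(1))]
  attr(out, "unallocated") <- if (length(unalloc)) dplyr::bind_rows(unalloc)
    else tibble(date = as.Date(character()), group = character(),
                count = numeric())
  attr(out, "filterset") <- filterset
  class(out) <- c("daily_totals", class(out))
  out
}
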