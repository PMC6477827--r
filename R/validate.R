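#' Protocol-integrity checks
#'
#' Runs the documented rule registry over a record table and returns every
#' triggered violation. Severities: \code{degrade} (the record keeps its
#' birds but is reclassified to a broader group), \code{warn} (reported,
#' data untouched), \code{reject} (record dropped; only used when a degrade
#' rule has no fallback group).
#'
#' Rules:
#' \describe{
#'   \item{ringtail_age}{Montagu's and Pallid Harrier records are only
#'     trusted with age information; without it they are degraded to
#'     MonPalHen. (Female- and juvenile-plumaged birds of these species are
#'     hard to separate; age is easier to judge than species.)}
#'   \item{large_eagle_age}{Greater Spotted, Steppe and Imperial Eagle cannot
#'     be identified without being aged; without age they are degraded to
#'     LargeEAGLE. Lesser Spotted Eagle is exempt by default: on-station
#'     identification is trusted even when age did not make it into the
#'     record.}
#'   \item{eagle_age_value}{Large eagles carry ad/imm/juv only (5th-calendar-
#'     year subadults are recorded as adult); a nonjuv value on a large eagle
#'     is age-protocol vocabulary and is warned about.}
#'   \item{morph_protocol}{A morph value on a species without a morph
#'     protocol (protocol species: Booted Eagle, Western Marsh-harrier,
#'     Steppe/Common Buzzard) is warned about.}
#'   \item{juv_sexed}{Juveniles of the harrier species are not sexed in the
#'     field; sex = m with age = juv is warned about.}
#'   \item{rare_flock}{number above the rare-species flock threshold for a
#'     configured list of scarce species is warned about (entry-error
#'     screen).}
#'   \item{imm_convention}{age = imm on HB or Black Kite conflicts with the
#'     juvenile/non-juvenile convention for those species; warned about.}
#' }
#'
#' @param records a count-record tibble.
#' @param hierarchy an \code{id_hierarchy}.
#' @param config a \code{protocol_config} carrying the rule knobs.
#' @return a tibble with columns id, rule, severity, message.
#' @export
check_records <- function(records, hierarchy = default_hierarchy(),
                          config = default_protocol()) {
  v <- list()
  add <- function(which, rule, severity, message) {
    if (any(which)) {
      v[[length(v) + 1]] <<- tibble(
        id = records$id[which], rule = rule, severity = severity,
        message = message)
    }
  }
  sp <- records$species
  no_age <- is.na(records$age)

  add(sp %in% config$ringtail_age_required & no_age,
      "ringtail_age", "degrade",
      "ringtail harrier without age information; degrade to MonPalHen")
  add(sp %in% config$large_eagle_age_required & no_age,
      "large_eagle_age", "degrade",
      "large eagle not identifiable without age; degrade to LargeEAGLE")
  add(sp %in% config$large_eagles & !no_age & records$age == "nonjuv",
      "eagle_age_value", "warn",
      "large eagles are aged ad/imm/juv (subadults recorded as adult)")
  add(!is.na(records$morph) & !sp %in% config$morph_species &
        !sp %in% hierarchy$groups,
      "morph_protocol", "warn",
      "morph recorded for a species without a morph protocol")
  add(sp %in% config$juv_not_sexed & !no_age & records$age == "juv" &
        !is.na(records$sex) & records$sex == "m",
      "juv_sexed", "warn",
      "juveniles of this species are not sexed in the field")
  add(sp %in% config$rare_species &
        records$number > config$rare_flock_threshold,
      "rare_flock", "warn",
      paste0("flock of a rare species larger than ",
             config$rare_flock_threshold, " individuals"))
  add(sp %in% c("HB", "BlackKite") & !no_age & records$age == "imm",
      "imm_convention", "warn",
      "species follows the juvenile/non-juvenile ageing convention")

  if (length(v)) dplyr::bind_rows(v) else
    tibble(id = integer(), rule = character(), severity = character(),
           message = character())
}

#' Check one record
#' @param r a one-row count-record tibble.
#' @inheritParams check_records
#' @return violations tibble (possibly empty).
#' @export
check_record <- function(r, hierarchy = default_hierarchy(),
                         config = default_protocol()) {
  check_records(r, hierarchy, config)
}

# fallback group per degrade rule
DEGRADE_FALLBACK <- c(ringtail_age = "MonPalHen",
                      large_eagle_age = "LargeEAGLE")

#' Degrade records that triggered a degrade rule
#'
#' The species is replaced by the designated fallback group (an ancestor of
#' the original species); every other field, including \code{number}, is
#' preserved, so individuals are conserved. Idempotent: a degraded record
#' triggers no further degrade rule.
#'
#' @param records count-record tibble (any subset).
#' @inheritParams check_records
#' @return the records with degraded species codes where required.
#' @export
degrade_record <- function(records, hierarchy = default_hierarchy(),
                           config = default_protocol()) {
  v <- check_records(records, hierarchy, config)
  v <- v[v$severity == "degrade", ]
  if (nrow(v)) {
    idx <- match(v$id, records$id)
    records$species[idx] <- unname(DEGRADE_FALLBACK[v$rule])
  }
  records
}

#' Run the full integrity pass
#'
#' Applies the rule registry to every record; degrade-level violations
#' reclassify the record to its fallback group, warnings never modify data,
#' and records whose degrade rule has no fallback are rejected. Output record
#' count equals input count minus rejects; total individuals are conserved by
#' degradation. Idempotent.
#'
#' @inheritParams check_records
#' @return list with \code{records} (processed), \code{violations} (tibble),
#'   \code{n_degraded}, \code{n_rejected}.
#' @export
integrity_pass <- function(records, hierarchy = default_hierarchy(),
                           config = default_protocol()) {
  violations <- check_records(records, hierarchy, config)
  deg <- violations[violations$severity == "degrade", ]
  out <- records
  n_degraded <- 0L
  if (nrow(deg)) {
    has_fb <- deg$rule %in% names(DEGRADE_FALLBACK)
    if (any(has_fb)) {
      idx <- match(deg$id[has_fb], out$id)
      out$species[idx] <- unname(DEGRADE_FALLBACK[deg$rule[has_fb]])
      n_degraded <- length(unique(idx))
    }
    if (any(!has_fb)) {
      violations$severity[match(deg$id[!has_fb], violations$id)] <- "reject"
      out <- out[!out$id %in% deg$id[!has_fb], ]
    }
  }
  list(records = out, violations = violations,
       n_degraded = n_degraded, n_rejected = nrow(records) - nrow(out))
}
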