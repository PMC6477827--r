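#' Detail rank of records
#'
#' When the same birds were recorded at both stations the more detailed
#' record is kept. A species-level identification always outranks a
#' group-level one regardless of attributes; within a level each of age, sex
#' and morph adds one point:
#' \code{rank = 4 * species_level + has_age + has_sex + has_morph}.
#'
#' @param records count-record tibble.
#' @param hierarchy an \code{id_hierarchy}.
#' @return integer vector of ranks (higher = more detailed).
#' @export
detail_rank <- function(records, hierarchy = default_hierarchy()) {
  base <- base_code(records$species, hierarchy)
  4L * as.integer(!is_group(base, hierarchy)) +
    as.integer(!is.na(records$age)) +
    as.integer(!is.na(records$sex)) +
    as.integer(!is.na(records$morph))
}

#' Could two records be a double count?
#'
#' True iff the records come from different stations on the same date, both
#' carry a time and a distance zone, their codes are taxon-compatible, the
#' time gap is within the window for the size class of the matched (more
#' general) taxon, the (station-1 zone, station-2 zone) pair lies in that
#' size class's overlap set, and neither record carries the observer
#' "single count" flag.
#'
#' @param a,b one-row count-record tibbles.
#' @param config a \code{protocol_config}.
#' @param hierarchy an \code{id_hierarchy}.
#' @return logical.
#' @export
is_candidate_pair <- function(a, b, config = default_protocol(),
                              hierarchy = default_hierarchy()) {
  if (a$station == b$station || a$date != b$date) return(FALSE)
  if (is.na(a$location) || is.na(b$location)) {
    warning("record without location excluded from double-count matching")
    return(FALSE)
  }
  if (is.na(a$time) || is.na(b$time)) return(FALSE)
  if (!taxon_compatible(a$species, b$species, hierarchy)) return(FALSE)
  flags <- parse_remark_flags(c(a$remark, b$remark))
  if (any(flags$single_count)) return(FALSE)
  taxon <- more_general(a$species, b$species, hierarchy)
  cls <- size_class(taxon, config)
  gap <- abs(time_to_minutes(a$time) - time_to_minutes(b$time))
  if (gap > config$window_minutes[[cls]]) return(FALSE)
  s1 <- if (a$station == 1L) a else b
  s2 <- if (a$station == 1L) b else a
  zone_pair_overlaps(s1$location, s2$location, cls, config)
}

# all candidate pairs between station-1 and station-2 records, vectorized
candidate_pairs <- function(records, config, hierarchy) {
  flags <- parse_remark_flags(records$remark)
  # age-protocol records are samples, not counts: never matched
  eligible <- !is.na(records$time) & !is.na(records$location) &
    !flags$single_count & records$dcremark == "" &
    !records$species %in% names(hierarchy$age_codes)
  r <- records[eligible, ]
  r$.dc <- parse_remark_flags(r$remark)$double_count
  r$.min <- time_to_minutes(r$time)
  a <- r[r$station == 1L, ]
  b <- r[r$station == 2L, ]
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)

  pairs <- merge(
    data.frame(ai = seq_len(nrow(a)), date = a$date),
    data.frame(bi = seq_len(nrow(b)), date = b$date)
  )
  if (nrow(pairs) == 0) return(NULL)
  gap <- abs(a$.min[pairs$ai] - b$.min[pairs$bi])
  pairs <- pairs[gap <= max(config$window_minutes), ]
  if (nrow(pairs) == 0) return(NULL)

  keep <- logical(nrow(pairs))
  taxon <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    sa <- a$species[pairs$ai[k]]
    sb <- b$species[pairs$bi[k]]
    if (!taxon_compatible(sa, sb, hierarchy)) next
    tx <- more_general(sa, sb, hierarchy)
    cls <- size_class(tx, config)
    if (abs(a$.min[pairs$ai[k]] - b$.min[pairs$bi[k]]) >
        config$window_minutes[[cls]]) next
    if (!zone_pair_overlaps(a$location[pairs$ai[k]], b$location[pairs$bi[k]],
                            cls, config)) next
    keep[k] <- TRUE
    taxon[k] <- tx
  }
  pairs <- pairs[keep, ]
  if (nrow(pairs) == 0) return(NULL)
  tibble(
    a_id = a$id[pairs$ai], b_id = b$id[pairs$bi],
    gap = abs(a$.min[pairs$ai] - b$.min[pairs$bi]),
    earlier = pmin(a$.min[pairs$ai], b$.min[pairs$bi]),
    taxon = taxon[keep],
    flagged = a$.dc[pairs$ai] | b$.dc[pairs$bi]
  )
}

#' Detect potential double counts
#'
#' Greedy chronological matching over all candidate pairs: candidates are
#' ordered by time gap, then earlier time of day, then lower record id;
#' records carrying the observer "double count" flag are matched with
#' priority. Each individual participates in at most one adjustment, so the
#' matched quantity is the minimum of the numbers still unmatched on each
#' side; a record can absorb several partners sequentially until its number
#' is exhausted. Flagged records are reported even when nothing is left to
#' match (quantity 0).
#'
#' Records already carrying a dcremark audit entry are excluded, which makes
#' the detect/apply cycle idempotent.
#'
#' @param records validated count-record tibble.
#' @param config a \code{protocol_config}.
#' @param hierarchy an \code{id_hierarchy}.
#' @return tibble of match candidates: a_id (station 1), b_id (station 2),
#'   gap (minutes), taxon (the more general code), quantity, flagged.
#' @export
match_records <- function(records, config = default_protocol(),
                          hierarchy = default_hierarchy()) {
  empty <- tibble(a_id = integer(), b_id = integer(), gap = numeric(),
                  taxon = character(), quantity = integer(),
                  flagged = logical())
  pairs <- candidate_pairs(records, config, hierarchy)
  if (is.null(pairs)) return(empty)
  pairs <- pairs[order(!pairs$flagged, pairs$gap, pairs$earlier,
                       pmin(pairs$a_id, pairs$b_id)), ]
  remaining <- stats::setNames(records$number, as.character(records$id))
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    qa <- remaining[[as.character(pairs$a_id[k])]]
    qb <- remaining[[as.character(pairs$b_id[k])]]
    q <- min(qa, qb)
    if (q < 1 && !pairs$flagged[k]) next
    q <- max(q, 0L)
    remaining[[as.character(pairs$a_id[k])]] <- qa - q
    remaining[[as.character(pairs$b_id[k])]] <- qb - q
    out[[k]] <- tibble(a_id = pairs$a_id[k], b_id = pairs$b_id[k],
                       gap = pairs$gap[k], taxon = pairs$taxon[k],
                       quantity = as.integer(q), flagged = pairs$flagged[k])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) dplyr::bind_rows(out) else empty
}

#' Apply double-count adjustments
#'
#' For each candidate the lower-ranked record's number is reduced by the
#' matched quantity (and the record dropped if it reaches zero); the
#' higher-ranked record is untouched. On a rank tie the species-level record
#' wins, then the earlier-entered (lower id) record. Both records receive a
#' dcremark audit entry linking the partner id with the quantity kept (+q) or
#' subtracted (-q).
#'
#' @param records count-record tibble.
#' @param candidates tibble from \code{\link{match_records}}.
#' @param hierarchy an \code{id_hierarchy}.
#' @return list with \code{records} (adjusted) and \code{report} (a
#'   dedup report: n_candidates, n_individuals_removed, per_species removal
#'   table, adjustments, unpartnered_flagged ids).
#' @export
apply_matches <- function(records, candidates,
                          hierarchy = default_hierarchy()) {
  out <- records
  rank <- stats::setNames(detail_rank(records, hierarchy),
                          as.character(records$id))
  adj <- vector("list", nrow(candidates))
  applied <- candidates[candidates$quantity >= 1L, , drop = FALSE]
  for (k in seq_len(nrow(applied))) {
    aid <- applied$a_id[k]; bid <- applied$b_id[k]
    q <- applied$quantity[k]
    ra <- rank[[as.character(aid)]]; rb <- rank[[as.character(bid)]]
    kept <- if (ra > rb) aid else if (rb > ra) bid else min(aid, bid)
    reduced <- if (kept == aid) bid else aid
    i_red <- match(reduced, out$id)
    i_kept <- match(kept, out$id)
    if (out$number[i_red] < q) stop("internal error: reduction below zero")
    out$number[i_red] <- out$number[i_red] - q
    out$north[i_red] <- min(out$north[i_red], out$number[i_red])
    out$dcremark[i_red] <- append_dcremark(out$dcremark[i_red], kept, -q)
    out$dcremark[i_kept] <- append_dcremark(out$dcremark[i_kept], reduced, q)
    adj[[k]] <- tibble(kept_id = kept, reduced_id = reduced,
                       quantity = q, taxon = applied$taxon[k])
  }
  adjustments <- if (nrow(applied)) dplyr::bind_rows(adj) else
    tibble(kept_id = integer(), reduced_id = integer(),
           quantity = integer(), taxon = character())
  dropped <- out$id[out$number == 0L]
  out <- out[out$number > 0L, ]
  per_species <- if (nrow(adjustments)) {
    stats::aggregate(quantity ~ taxon, data = adjustments, FUN = sum)
  } else data.frame(taxon = character(), quantity = integer())
  report <- list(
    n_candidates = nrow(candidates),
    n_individuals_removed = sum(adjustments$quantity),
    per_species = as_tibble(per_species),
    adjustments = adjustments,
    dropped_ids = dropped,
    unpartnered_flagged = candidates$a_id[candidates$flagged &
                                            candidates$quantity == 0L]
  )
  list(records = out, report = report)
}

append_dcremark <- function(cur, partner_id, signed_q) {
  entry <- paste0(partner_id, ":", ifelse(signed_q >= 0, "+", "-"),
                  abs(signed_q))
  ifelse(cur == "", entry, paste(cur, entry, sep = ";"))
}

#' Detect and remove double counts
#'
#' Composition of \code{\link{match_records}} and
#' \code{\link{apply_matches}}. The procedure is deliberately conservative
#' (it may match records that were in fact distinct birds), so the output
#' estimates the minimum number of individuals passing. Idempotent: adjusted
#' records are linked through dcremark and excluded from re-matching.
#'
#' @inheritParams match_records
#' @return list with \code{records} and \code{report} as in
#'   \code{\link{apply_matches}}.
#' @export
remove_double_counts <- function(records, config = default_protocol(),
                                 hierarchy = default_hierarchy()) {
  candidates <- match_records(records, config, hierarchy)
  apply_matches(records, candidates, hierarchy)
}
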