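#' @importFrom tibble tibble as_tibble
NULL

# canonical column order of the count-table schema
RECORD_COLUMNS <- c("id", "date", "time", "species", "number", "north",
                    "station", "location", "age", "sex", "morph", "health",
                    "remark", "dcremark", "filter")

ZONE_LEVELS <- c("W3", "W2", "W1", "O", "E1", "E2", "E3", "E4")
AGE_LEVELS <- c("ad", "imm", "nonjuv", "juv")
SEX_LEVELS <- c("f", "fc", "m")
MORPH_LEVELS <- c("dark", "light", "ful", "mel", "leu")
HEALTH_LEVELS <- c("kil", "inj")

#' Construct a count-record table
#'
#' A record is one row: a group of one or more birds of identical
#' classification passing one station. A row can be a solitary bird, a whole
#' flock or stream, or a subset of a larger flock (birds of different age,
#' sex or morph are entered separately), so \code{number} carries no
#' flock-size meaning.
#'
#' @param id integer record keys (unique).
#' @param date \code{Date} (or YYYY-MM-DD strings).
#' @param time times of day as "hh:mm:ss" strings (naive local time).
#' @param species species / morphological-group / age-protocol codes.
#' @param number individuals in the record, integer >= 1.
#' @param north individuals moving north (reverse migration), 0 <= north <=
#'   number.
#' @param station 1 or 2.
#' @param location distance zone W3..O..E4, or NA.
#' @param age one of ad, imm, nonjuv, juv, or NA.
#' @param sex one of f, fc, m, or NA.
#' @param morph one of dark, light, ful, mel, leu, or NA.
#' @param health kil, inj, or NA.
#' @param remark free text ("" if none).
#' @param dcremark double-count audit trail ("" if none).
#' @param filter 0 non-standardized, 1 standardized, 2 standardized early
#'   morning.
#' @return a tibble with the canonical 15 columns.
#' @export
count_records <- function(id, date, time, species, number,
                          north = 0L, station = 1L, location = NA_character_,
                          age = NA_character_, sex = NA_character_,
                          morph = NA_character_, health = NA_character_,
                          remark = "", dcremark = "", filter = 1L) {
  tibble(
    id = as.integer(id),
    date = as.Date(date),
    time = as.character(time),
    species = as.character(species),
    number = as.integer(number),
    north = as.integer(north),
    station = as.integer(station),
    location = as.character(location),
    age = as.character(age),
    sex = as.character(sex),
    morph = as.character(morph),
    health = as.character(health),
    remark = as.character(remark),
    dcremark = as.character(dcremark),
    filter = as.integer(filter)
  )
}

# "hh:mm:ss" -> minutes after midnight (numeric, with seconds as fraction)
time_to_minutes <- function(time) {
  h <- as.numeric(substr(time, 1, 2))
  m <- as.numeric(substr(time, 4, 5))
  s <- as.numeric(substr(time, 7, 8))
  s[is.na(s)] <- 0
  h * 60 + m + s / 60
}

# minutes after midnight -> "hh:mm:ss"
minutes_to_time <- function(min) {
  min <- round(min * 60) / 60
  h <- floor(min / 60)
  m <- floor(min - 60 * h)
  s <- round((min - 60 * h - m) * 60)
  sprintf("%02d:%02d:%02d", h, m, s)
}

valid_time <- function(time) {
  grepl("^([01][0-9]|2[0-3]):[0-5][0-9](:[0-5][0-9])?$", time)
}

empty_records <- function() {
  count_records(integer(), as.Date(character()), character(), character(),
                integer())[0, ]
}
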