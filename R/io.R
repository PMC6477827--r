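#' Read a count table
#'
#' Reads a delimited text file (or literal text) in the 15-column count
#' schema. The delimiter is auto-detected among comma, semicolon and tab.
#' Column order is free; the header names decide. Dates must be YYYY-MM-DD
#' and times hh:mm:ss. Rows violating the schema are rejected row-wise and
#' reported (or, in strict mode, abort the read). Empty strings and literal
#' "NA" both read as absent.
#'
#' @param source a file path, connection, or literal text.
#' @param hierarchy an \code{id_hierarchy} used to validate species codes.
#' @param strict if TRUE, any row-level violation is an error.
#' @return a list with \code{records} (tibble) and \code{report} (list with
#'   \code{n_rows}, \code{n_accepted} and an \code{issues} tibble of
#'   row/kind/message).
#' @export
read_count_table <- function(source, hierarchy = default_hierarchy(),
                             strict = FALSE) {
  delim <- detect_delim(source)
  raw <- readr::read_delim(source, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE)

  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[RECORD_COLUMNS]
  n_rows <- nrow(raw)
  if (n_rows == 0) {
    return(list(records = empty_records(),
                report = list(n_rows = 0L, n_accepted = 0L,
                              issues = issue_tbl())))
  }

  blank <- function(x) is.na(x) | x == "" | x == "NA"
  issues <- list()
  bad <- rep(FALSE, n_rows)
  flag <- function(which, kind, message) {
    if (any(which)) {
      issues[[length(issues) + 1]] <<- tibble(
        row = which(which), kind = kind, message = message)
      bad[which] <<- TRUE
    }
  }

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  flag(is.na(date), "date", "unparseable date (expect YYYY-MM-DD)")
  flag(!valid_time(raw$time), "time", "unparseable time (expect hh:mm:ss)")

  number <- suppressWarnings(as.integer(raw$number))
  flag(is.na(number) | number < 1, "number", "number must be an integer >= 1")

  known <- c(names(hierarchy$parent), names(hierarchy$age_codes))
  flag(!raw$species %in% known, "species", "unknown species code")

  north <- suppressWarnings(as.integer(raw$north))
  north[blank(raw$north)] <- 0L
  flag(is.na(north) | north < 0 | (!is.na(number) & north > number),
       "north", "north must be an integer with 0 <= north <= number")

  station <- suppressWarnings(as.integer(raw$station))
  flag(is.na(station) | !station %in% c(1L, 2L), "station",
       "station must be 1 or 2")

  check_enum <- function(col, levels, label) {
    x <- raw[[col]]
    flag(!blank(x) & !x %in% levels, col,
         paste0(label, " (value set is ",
                paste(levels, collapse = ", "), ")"))
    ifelse(blank(x), NA_character_, x)
  }
  location <- check_enum("location", ZONE_LEVELS, "invalid distance zone")
  age <- check_enum("age", AGE_LEVELS, "invalid age")
  sex <- check_enum("sex", SEX_LEVELS, "invalid sex")
  morph <- check_enum("morph", MORPH_LEVELS, "invalid morph")
  health <- check_enum("health", HEALTH_LEVELS, "invalid health")

  filter <- suppressWarnings(as.integer(raw$filter))
  flag(is.na(filter) | !filter %in% 0:2, "filter", "filter must be 0, 1 or 2")

  idv <- suppressWarnings(as.integer(raw$id))
  flag(is.na(idv), "id", "id must be an integer")
  dup <- duplicated(idv) & !is.na(idv)
  flag(dup, "id", "duplicate record id")

  issues <- if (length(issues)) dplyr::bind_rows(issues) else issue_tbl()
  if (strict && nrow(issues)) {
    stop("invalid rows in count table: ",
         paste(utils::head(paste0("row ", issues$row, " [", issues$kind, "] ",
                                  issues$message), 5), collapse = "; "),
         call. = FALSE)
  }

  keep <- !bad
  records <- tibble(
    id = idv, date = date, time = raw$time, species = raw$species,
    number = number, north = north, station = station, location = location,
    age = age, sex = sex, morph = morph, health = health,
    remark = ifelse(blank(raw$remark), "", raw$remark),
    dcremark = ifelse(blank(raw$dcremark), "", raw$dcremark),
    filter = filter
  )[keep, ]

  list(records = records,
       report = list(n_rows = n_rows, n_accepted = sum(keep),
                     issues = issues))
}

issue_tbl <- function() {
  tibble(row = integer(), kind = character(), message = character())
}

detect_delim <- function(source) {
  header <- tryCatch(readr::read_lines(source, n_max = 1), error = function(e) "")
  if (length(header) == 0) return(",")
  counts <- c(`,` = lengths(regmatches(header, gregexpr(",", header))),
              `;` = lengths(regmatches(header, gregexpr(";", header))),
              `\t` = lengths(regmatches(header, gregexpr("\t", header))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Write a count table
#'
#' Writes comma-separated text in canonical column order. Absent values are
#' written as empty strings. Reading the file back reproduces the records
#' field for field.
#'
#' @param records a count-record tibble.
#' @param destination file path or connection.
#' @export
write_count_table <- function(records, destination) {
  out <- records[RECORD_COLUMNS]
  out$date <- format(out$date, "%Y-%m-%d")
  for (col in c("location", "age", "sex", "morph", "health")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", out[[col]])
  }
  readr::write_csv(out, destination, na = "", progress = FALSE)
  invisible(destination)
}

#' Parse observer flags out of a remark
#'
#' Counters may flag a record "single count" (its correctness across stations
#' was settled by radio, exclude from double-count detection) or "double
#' count" (a recognized duplicate left in on purpose as a detection control).
#' Tokens are matched case-insensitively, with or without the space.
#'
#' @param remark character vector of free-text remarks.
#' @return a tibble with logical columns \code{single_count} and
#'   \code{double_count}.
#' @export
parse_remark_flags <- function(remark) {
  remark <- ifelse(is.na(remark), "", remark)
  tibble(
    single_count = grepl("single ?count", remark, ignore.case = TRUE),
    double_count = grepl("double ?count", remark, ignore.case = TRUE)
  )
}
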