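# Partial-date helpers.
#
# FAERS date fields are digit strings: YYYYMMDD (day precision), YYYYMM
# (month precision) or YYYY (year precision). "" / NA = missing. Dates are
# kept as strings throughout ingestion so partial values survive round-trips;
# arithmetic is only ever done on day-precision values.

#' Precision of a FAERS-style date string
#'
#' @param x character vector of date strings (`YYYYMMDD`, `YYYYMM`, `YYYY`,
#'   `""` or `NA`).
#' @return character vector with values `"day"`, `"month"`, `"year"` or `NA`
#'   for missing/unparseable entries.
#' @export
date_precision <- function(x) {
  x <- as.character(x)
  p <- rep(NA_character_, length(x))
  ok <- !is.na(x) & grepl("^[0-9]+$", x)
  p[ok & nchar(x) == 8L] <- "day"
  p[ok & nchar(x) == 6L] <- "month"
  p[ok & nchar(x) == 4L] <- "year"
  p
}

# numeric day count (days since epoch) for day-precision dates, NA otherwise
date_to_days <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(date_precision(x)) & date_precision(x) == "day"
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y%m%d")
    out[ok] <- as.numeric(d)
  }
  out
}

# YYYYMMDD string k days after x (x must be day precision)
date_add_days <- function(x, k) {
  d <- as.Date(as.character(x), format = "%Y%m%d") + k
  format(d, "%Y%m%d")
}

# sortable numeric key: right-pad partial dates with zeros; missing -> 0
date_sort_key <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !grepl("^[0-9]{4,8}$", x)] <- ""
  pad <- strrep("0", pmax(0L, 8L - nchar(x)))
  suppressWarnings(as.numeric(paste0(x, pad)))
}

#' Compare two possibly partial dates at their shared precision
#'
#' Two dates are only compared at the coarsest precision they share: a
#' month-precision start and a day-precision event are compared on
#' `YYYYMM`; equality at the shared precision is treated as non-violating.
#' This conservative rule avoids excluding reports whose ordering cannot be
#' established from the recorded precision.
#'
#' @param start,event character vectors of date strings.
#' @return character vector: `"before"` if `event` strictly precedes
#'   `start` at the shared precision, `"ok"` if not, `"incomparable"` if
#'   either date is missing/unparseable.
#' @export
compare_partial_dates <- function(start, event) {
  start <- as.character(start)
  event <- as.character(event)
  ps <- date_precision(start)
  pe <- date_precision(event)
  out <- rep("incomparable", length(start))
  comp <- !is.na(ps) & !is.na(pe)
  if (any(comp)) {
    nch <- pmin(nchar(start[comp]), nchar(event[comp]))
    s <- as.numeric(substr(start[comp], 1L, nch))
    e <- as.numeric(substr(event[comp], 1L, nch))
    out[comp] <- ifelse(e < s, "before", "ok")
  }
  out
}

# day difference event - start; NA unless both carry day precision
days_between <- function(start, event) {
  date_to_days(event) - date_to_days(start)
}
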