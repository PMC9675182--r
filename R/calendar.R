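#' Coerce to a civil calendar date
#'
#' Dates throughout the package are timezone-free civil dates; no sub-daily
#' data are supported. Unparseable inputs are a hard error, never silent `NA`.
#'
#' @param x character (ISO-8601, `YYYY-MM-DD`) or `Date`.
#' @param what label used in error messages.
#' @return a `Date` vector.
#' @keywords internal
as_civil_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("unparseable %s at position %d: '%s' (expected YYYY-MM-DD)",
                 what, bad[1], as.character(x)[bad[1]]), call. = FALSE)
  }
  out
}

#' Inclusive day count between two dates
#'
#' Number of calendar days in `[start, end]` including both endpoints,
#' leap-year aware. The 2014-01-01 to 2019-12-31 study window, for example,
#' spans 2191 days (five 365-day years plus the 366-day year 2016).
#'
#' @param start,end dates (`Date` or ISO-8601 character), recycled to a
#'   common length.
#' @return integer vector of day counts.
#' @examples
#' inclusive_day_count("2014-01-01", "2019-12-31") # 2191
#' inclusive_day_count("2016-02-28", "2016-03-01") # 3 (leap year)
#' @export
inclusive_day_count <- function(start, end) {
  start <- as_civil_date(start, "start date")
  end <- as_civil_date(end, "end date")
  if (any(end < start)) {
    stop("start date must not be after end date", call. = FALSE)
  }
  as.integer(end - start) + 1L
}

#' Austral season of a calendar date
#'
#' Southern-hemisphere seasons by calendar month: DJF summer, MAM autumn,
#' JJA winter, SON spring. Events elsewhere in the package are attributed
#' to the season of the day (or of the event start date), never shifted.
#'
#' @param date `Date` or ISO-8601 character vector.
#' @return factor with levels `summer`, `autumn`, `winter`, `spring`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as_civil_date(date), "%m"))
  lab <- c("summer", "summer", "autumn", "autumn", "autumn",
           "winter", "winter", "winter", "spring", "spring",
           "spring", "summer")[m]
  factor(lab, levels = austral_seasons())
}

#' @rdname season_of
#' @export
austral_seasons <- function() c("summer", "autumn", "winter", "spring")

#' Daily date sequence spanning a period (inclusive)
#' @keywords internal
date_seq <- function(start, end) {
  seq(as_civil_date(start), as_civil_date(end), by = "day")
}
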