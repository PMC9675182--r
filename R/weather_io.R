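#' Construct a daily temperature series for one district
#'
#' A `daily_series` is a tibble with one row per calendar day over
#' `[period_start, period_end]`: columns `district_id`, `date`, `tmax`,
#' `tmin` (degrees C, `NA` where unobserved). Days absent from the input are
#' filled in as explicit missing records — missing data are retained, never
#' interpolated, because interpolation would fabricate exposure days.
#'
#' @param district_id single district identifier.
#' @param date vector of dates (`Date` or ISO-8601 character), unique.
#' @param tmax,tmin daily maximum/minimum temperature in degrees C; `NA`
#'   allowed.
#' @param period_start,period_end period bounds; default to the range of
#'   `date`.
#' @return a `daily_series` tibble with attributes `district_id`,
#'   `period_start`, `period_end`.
#' @export
daily_series <- function(district_id, date, tmax = NA_real_, tmin = NA_real_,
                         period_start = NULL, period_end = NULL) {
  stopifnot(length(district_id) == 1, !is.na(district_id))
  date <- as_civil_date(date)
  if (anyDuplicated(date) > 0) {
    stop(sprintf("duplicate date(s) for district %s: %s", district_id,
                 as.character(date[duplicated(date)][1])), call. = FALSE)
  }
  n <- length(date)
  tmax <- rep_len(as.numeric(tmax), n)
  tmin <- rep_len(as.numeric(tmin), n)
  both <- !is.na(tmax) & !is.na(tmin)
  if (any(both & tmax < tmin)) {
    i <- which(both & tmax < tmin)[1]
    stop(sprintf("tmax < tmin on %s for district %s; sanitise first (see read_daily_csv)",
                 as.character(date[i]), district_id), call. = FALSE)
  }
  period_start <- if (is.null(period_start)) min(date) else as_civil_date(period_start)
  period_end <- if (is.null(period_end)) max(date) else as_civil_date(period_end)
  if (any(date < period_start) || any(date > period_end)) {
    stop("dates fall outside [period_start, period_end]", call. = FALSE)
  }
  full <- date_seq(period_start, period_end)
  i <- match(full, date)
  out <- tibble::tibble(
    district_id = as.character(district_id),
    date = full,
    tmax = tmax[i],
    tmin = tmin[i]
  )
  structure(out,
            class = c("daily_series", class(out)),
            district_id = as.character(district_id),
            period_start = period_start,
            period_end = period_end)
}

#' Validate the daily-series invariants
#'
#' Checks: single district; strictly increasing dates covering every day of
#' the period exactly once; `tmax >= tmin` wherever both are present.
#'
#' @param x a `daily_series`.
#' @return `x`, invisibly; hard error on any violation.
#' @export
validate_daily_series <- function(x) {
  stopifnot(inherits(x, "daily_series"))
  did <- unique(x$district_id)
  if (length(did) != 1) stop("series must contain exactly one district", call. = FALSE)
  full <- date_seq(attr(x, "period_start"), attr(x, "period_end"))
  if (length(full) != nrow(x) || any(x$date != full)) {
    stop("series calendar is not one record per day over the period", call. = FALSE)
  }
  both <- !is.na(x$tmax) & !is.na(x$tmin)
  if (any(x$tmax[both] < x$tmin[both])) {
    stop("tmax < tmin with both values present", call. = FALSE)
  }
  invisible(x)
}

#' Fraction of days with any missing temperature
#' @param x a `daily_series`.
#' @return numeric scalar in [0, 1].
#' @export
missing_fraction <- function(x) {
  mean(is.na(x$tmax) | is.na(x$tmin))
}

#' Read daily district temperatures from a long-format CSV
#'
#' Expects one row per (district, day) with columns mapped by `schema`.
#' Quality control applied on ingestion:
#' \itemize{
#'   \item duplicate (district, date) rows are a hard error;
#'   \item rows with `tmax < tmin` are treated as sensor error — both values
#'     set missing, the row counted in `n_flagged`, and a warning raised;
#'   \item calendar gaps are filled with explicit missing records so every
#'     series covers its period day by day.
#' }
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical names
#'   `district_id`, `date`, `tmax`, `tmin` to the file's column headers.
#' @param meta optional district metadata (tibble from
#'   [read_district_meta()]); districts absent from it are a hard error.
#' @param period_start,period_end optional common period bounds applied to
#'   every district; default to each district's own date range.
#' @return list with `series` (named list of [daily_series()]) and `qc`
#'   (tibble: `district_id`, `n_days`, `n_missing`, `missing_frac`,
#'   `n_flagged`).
#' @export
read_daily_csv <- function(path,
                           schema = c(district_id = "district_id", date = "date",
                                      tmax = "tmax", tmin = "tmin"),
                           meta = NULL,
                           period_start = NULL, period_end = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  need <- c("district_id", "date", "tmax", "tmin")
  if (!all(need %in% names(schema))) {
    stop("schema must name district_id, date, tmax and tmin columns", call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0) stop(sprintf("empty input file: %s", path), call. = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- tibble::tibble(
    district_id = raw[[schema[["district_id"]]]],
    date = as_civil_date(raw[[schema[["date"]]]], "date"),
    tmax = parse_temperature(raw[[schema[["tmax"]]]]),
    tmin = parse_temperature(raw[[schema[["tmin"]]]])
  )
  dup <- duplicated(df[, c("district_id", "date")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate record for district %s on %s (row %d)",
                 df$district_id[i], as.character(df$date[i]), i), call. = FALSE)
  }
  if (!is.null(meta)) {
    unknown <- setdiff(unique(df$district_id), meta$district_id)
    if (length(unknown) > 0) {
      stop(sprintf("district(s) not in metadata: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  inverted <- !is.na(df$tmax) & !is.na(df$tmin) & df$tmax < df$tmin
  if (any(inverted)) {
    warning(sprintf("%d row(s) with tmax < tmin set to missing (sensor error)",
                    sum(inverted)), call. = FALSE)
    df$tmax[inverted] <- NA_real_
    df$tmin[inverted] <- NA_real_
  }
  ids <- unique(df$district_id)
  series <- lapply(ids, function(id) {
    d <- df[df$district_id == id, ]
    daily_series(id, d$date, d$tmax, d$tmin,
                 period_start = period_start, period_end = period_end)
  })
  names(series) <- ids
  flagged <- tapply(inverted, df$district_id, sum)
  qc <- tibble::tibble(
    district_id = ids,
    n_days = unname(vapply(series, nrow, integer(1))),
    n_missing = unname(vapply(series, function(s) sum(is.na(s$tmax) | is.na(s$tmin)),
                              integer(1))),
    n_flagged = unname(as.integer(flagged[ids]))
  )
  qc$missing_frac <- qc$n_missing / qc$n_days
  list(series = series, qc = qc[, c("district_id", "n_days", "n_missing",
                                    "missing_frac", "n_flagged")])
}

parse_temperature <- function(x) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  out
}

#' Write daily series to a long-format CSV
#'
#' Inverse of [read_daily_csv()]: the written file re-reads to the same
#' dates, values and missingness pattern.
#'
#' @param series a `daily_series` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(series, path) {
  if (inherits(series, "daily_series")) series <- list(series)
  df <- dplyr::bind_rows(lapply(series, as.data.frame))
  df$date <- as.character(df$date)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate district metadata
#'
#' One row per district: identifier, province, minimum mortality temperature
#' (MMT, degrees C — the mean daily temperature of lowest mortality, below
#' which days are excluded from heatwave analysis), centroid coordinates and
#' a coastal flag. All invariant violations are hard errors: MMT outside
#' [10, 45] degrees C, coordinates off the globe, duplicate district ids.
#'
#' @param path CSV with columns `district_id`, `province`, `mmt`, `lat`,
#'   `lon`, `coastal`.
#' @return tibble of validated metadata.
#' @export
read_district_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("district_id", "province", "mmt", "lat", "lon", "coastal")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("metadata missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  meta <- tibble::tibble(
    district_id = as.character(raw$district_id),
    province = as.character(raw$province),
    mmt = as.numeric(raw$mmt),
    lat = as.numeric(raw$lat),
    lon = as.numeric(raw$lon),
    coastal = parse_flag(raw$coastal)
  )
  validate_district_meta(meta)
}

#' @rdname read_district_meta
#' @param meta a metadata tibble to validate in place.
#' @export
validate_district_meta <- function(meta) {
  if (anyDuplicated(meta$district_id) > 0) {
    stop(sprintf("duplicate district_id: %s",
                 meta$district_id[duplicated(meta$district_id)][1]), call. = FALSE)
  }
  if (any(is.na(meta$mmt)) || any(meta$mmt < 10 | meta$mmt > 45)) {
    stop("mmt must lie in [10, 45] degrees C", call. = FALSE)
  }
  if (any(is.na(meta$lat)) || any(abs(meta$lat) > 90)) {
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  }
  if (any(is.na(meta$lon)) || any(abs(meta$lon) > 180)) {
    stop("longitude must lie in [-180, 180]", call. = FALSE)
  }
  if (any(is.na(meta$coastal))) stop("coastal flag must be TRUE/FALSE", call. = FALSE)
  meta
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}
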