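#' Bilinear interpolation on a regular lat/lon grid
#'
#' Standard bilinear weighting of the four grid nodes surrounding the query
#' point. Points on a node return that node's value exactly; points outside
#' the grid's bounding box are a hard error (no extrapolation).
#'
#' @param grid list with `lats`, `lons` (strictly increasing numeric vectors)
#'   and `values` (matrix, rows indexed by `lats`, columns by `lons`).
#' @param lat,lon query coordinates in decimal degrees (vectors, recycled to
#'   common length).
#' @return numeric vector of interpolated values.
#' @export
bilinear_interpolate <- function(grid, lat, lon) {
  lats <- grid$lats
  lons <- grid$lons
  v <- grid$values
  stopifnot(is.matrix(v), nrow(v) == length(lats), ncol(v) == length(lons),
            all(diff(lats) > 0), all(diff(lons) > 0))
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)
  if (any(lat < lats[1] | lat > lats[length(lats)] |
          lon < lons[1] | lon > lons[length(lons)])) {
    stop("query point outside the anomaly grid; no extrapolation", call. = FALSE)
  }
  i <- pmin(findInterval(lat, lats), length(lats) - 1L)
  j <- pmin(findInterval(lon, lons), length(lons) - 1L)
  i <- pmax(i, 1L)
  j <- pmax(j, 1L)
  u <- (lat - lats[i]) / (lats[i + 1L] - lats[i])
  w <- (lon - lons[j]) / (lons[j + 1L] - lons[j])
  v[cbind(i, j)] * (1 - u) * (1 - w) +
    v[cbind(i, j + 1L)] * (1 - u) * w +
    v[cbind(i + 1L, j)] * u * (1 - w) +
    v[cbind(i + 1L, j + 1L)] * u * w
}

#' Construct a per-district anomaly field
#'
#' The canonical anomaly representation: scenario-labelled additive deltas
#' (degrees C) for `tmax` and `tmin`, per district, at monthly or constant
#' time resolution (`month = NA` means the delta applies year-round).
#'
#' @param scenario scenario label, e.g. `"RCP4.5"`.
#' @param deltas tibble with columns `variable` (`"tmax"`/`"tmin"`),
#'   `district_id`, `month` (1-12 or `NA`), `delta` (degrees C, finite).
#' @return tibble of class `anomaly_field` with a `scenario` column.
#' @export
anomaly_field <- function(scenario, deltas) {
  stopifnot(all(c("variable", "district_id", "month", "delta") %in% names(deltas)))
  if (!all(deltas$variable %in% c("tmax", "tmin"))) {
    stop("anomaly variable must be 'tmax' or 'tmin'", call. = FALSE)
  }
  if (any(!is.finite(deltas$delta))) stop("anomaly deltas must be finite", call. = FALSE)
  bad_month <- !is.na(deltas$month) & !(deltas$month %in% 1:12)
  if (any(bad_month)) stop("month must be 1..12 or NA", call. = FALSE)
  out <- tibble::tibble(scenario = as.character(scenario),
                        variable = deltas$variable,
                        district_id = as.character(deltas$district_id),
                        month = as.integer(deltas$month),
                        delta = as.numeric(deltas$delta))
  class(out) <- c("anomaly_field", class(out))
  out
}

#' Interpolate gridded anomalies to district centroids
#'
#' Gridded scenario anomalies (one regular lat/lon grid per variable, as from
#' a 1-degree GCM anomaly product) are bilinearly interpolated to each
#' district centroid once, then treated as year-round district deltas.
#'
#' @param scenario scenario label.
#' @param tmax_grid,tmin_grid grids as accepted by [bilinear_interpolate()].
#' @param meta district metadata tibble (`district_id`, `lat`, `lon`).
#' @return an [anomaly_field()].
#' @export
anomaly_from_grid <- function(scenario, tmax_grid, tmin_grid, meta) {
  dx <- bilinear_interpolate(tmax_grid, meta$lat, meta$lon)
  dn <- bilinear_interpolate(tmin_grid, meta$lat, meta$lon)
  anomaly_field(scenario, tibble::tibble(
    variable = rep(c("tmax", "tmin"), each = nrow(meta)),
    district_id = rep(meta$district_id, 2),
    month = NA_integer_,
    delta = c(dx, dn)
  ))
}

#' Read a long-format anomaly CSV
#'
#' Columns: `scenario`, `variable`, `district_id`, `month` (blank for
#' year-round), `delta`.
#'
#' @param path CSV path.
#' @return named list of [anomaly_field()], one per scenario in the file.
#' @export
read_anomaly_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "variable", "district_id", "month", "delta")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("anomaly file missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  split_rows <- split(raw, raw$scenario)
  lapply(split_rows, function(d) {
    anomaly_field(d$scenario[1], tibble::tibble(
      variable = d$variable, district_id = as.character(d$district_id),
      month = suppressWarnings(as.integer(d$month)), delta = d$delta
    ))
  })
}

#' Apply scenario anomalies to an observed series (delta-change method)
#'
#' Projects a future daily series by adding the scenario's additive deltas to
#' the observed series: `future_t(d) = observed_t(analogue of d) + delta`.
#' The observed calendar is cycled to cover the target period, aligning by
#' month and day (the base year for target year `y` is
#' `base_years[(y - first_target_year) mod n_base + 1]`; 29 February in a
#' future leap year maps from 28 February when the source year lacks it).
#' tmax and tmin are perturbed by their own deltas; missing observed days
#' stay missing; monthly deltas broadcast to all days of the month. Any day
#' whose perturbed tmax falls below its perturbed tmin is set missing with a
#' warning.
#'
#' @param series observed [daily_series()] spanning whole calendar years.
#' @param field an [anomaly_field()] covering the series' district.
#' @param meta one-row metadata for the district (used for its id).
#' @param target_period length-2 vector (start, end) of the projection
#'   period.
#' @return a future [daily_series()] over `target_period`.
#' @export
apply_anomaly <- function(series, field, meta, target_period) {
  stopifnot(inherits(series, "daily_series"))
  did <- attr(series, "district_id")
  ps <- attr(series, "period_start")
  pe <- attr(series, "period_end")
  if (format(ps, "%m-%d") != "01-01" || format(pe, "%m-%d") != "12-31") {
    stop("base series must span whole calendar years (Jan 1 to Dec 31)", call. = FALSE)
  }
  f <- field[field$district_id == did, ]
  if (nrow(f) == 0) {
    stop(sprintf("anomaly field has no deltas for district %s", did), call. = FALSE)
  }
  dates <- date_seq(target_period[1], target_period[2])
  ty <- as.integer(format(dates, "%Y"))
  tm <- as.integer(format(dates, "%m"))
  td <- as.integer(format(dates, "%d"))
  base_years <- as.integer(format(ps, "%Y")):as.integer(format(pe, "%Y"))
  byear <- base_years[((ty - ty[1]) %% length(base_years)) + 1L]
  bdate <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", byear, tm, td)))
  feb29 <- is.na(bdate)
  if (any(feb29)) {
    bdate[feb29] <- as.Date(sprintf("%04d-02-28", byear[feb29]))
  }
  idx <- match(bdate, series$date)
  if (anyNA(idx)) {
    stop("base series does not cover the calendar analogue of the target period",
         call. = FALSE)
  }
  d_tmax <- delta_for_dates(f, "tmax", tm)
  d_tmin <- delta_for_dates(f, "tmin", tm)
  tmax_f <- series$tmax[idx] + d_tmax
  tmin_f <- series$tmin[idx] + d_tmin
  bad <- !is.na(tmax_f) & !is.na(tmin_f) & tmax_f < tmin_f
  if (any(bad)) {
    warning(sprintf("%d projected day(s) with tmax < tmin set to missing", sum(bad)),
            call. = FALSE)
    tmax_f[bad] <- NA_real_
    tmin_f[bad] <- NA_real_
  }
  daily_series(did, dates, tmax_f, tmin_f,
               period_start = dates[1], period_end = dates[length(dates)])
}

delta_for_dates <- function(field, variable, months) {
  f <- field[field$variable == variable, ]
  if (nrow(f) == 0) {
    stop(sprintf("anomaly field lacks deltas for variable %s", variable),
         call. = FALSE)
  }
  if (all(is.na(f$month))) {
    if (nrow(f) != 1) stop("multiple year-round deltas for one district/variable",
                           call. = FALSE)
    return(rep(f$delta, length(months)))
  }
  if (!all(1:12 %in% f$month)) {
    stop(sprintf("monthly anomaly field for %s does not cover all 12 months", variable),
         call. = FALSE)
  }
  f$delta[match(months, f$month)]
}

#' Project all districts under one scenario
#'
#' @param series_list named list of observed [daily_series()].
#' @param field an [anomaly_field()].
#' @param meta metadata tibble.
#' @param target_period length-2 projection period.
#' @return named list of future [daily_series()].
#' @export
apply_anomaly_all <- function(series_list, field, meta, target_period) {
  out <- lapply(names(series_list), function(id) {
    apply_anomaly(series_list[[id]], field, meta[meta$district_id == id, ],
                  target_period)
  })
  names(out) <- names(series_list)
  out
}

#' Percent change between observed and future counts
#'
#' `100 * (future - observed) / observed`, reported rounded to the nearest
#' whole percent alongside the unrounded value (the presentation convention
#' for scenario increases such as 80% and 87%). Undefined when
#' `observed = 0`: reported as `NA`, never infinity.
#'
#' @param observed,future non-negative counts (vectors, recycled).
#' @return tibble (`observed`, `future`, `pct_raw`, `pct_rounded`).
#' @export
pct_change <- function(observed, future) {
  n <- max(length(observed), length(future))
  observed <- rep_len(as.numeric(observed), n)
  future <- rep_len(as.numeric(future), n)
  raw <- ifelse(observed > 0, 100 * (future - observed) / observed, NA_real_)
  tibble::tibble(observed = observed, future = future,
                 pct_raw = raw, pct_rounded = round(raw))
}

#' Compare observed and scenario event sets
#'
#' Per-group observed vs future totals with percent change, reporting event
#' counts and event-days as separate measures (printed scenario summaries
#' are ambiguous about which unit they show, so both are always available).
#'
#' @param observed_events event tibble under observed climate.
#' @param future_events event tibble for one scenario, or a named list of
#'   event tibbles (names are scenario labels).
#' @param by grouping key passed to [summarise_events()].
#' @param levels optional zero-fill group values.
#' @param scenario label used when `future_events` is a single tibble.
#' @return tibble (`scenario`, `group`, `measure` in `events`/`event_days`,
#'   `observed`, `future`, `pct_raw`, `pct_rounded`).
#' @export
compare_scenarios <- function(observed_events, future_events, by = "season",
                              levels = NULL, scenario = "scenario") {
  if (!is.list(future_events) || is.data.frame(future_events)) {
    future_events <- stats::setNames(list(future_events), scenario)
  }
  if (is.null(levels)) {
    col <- switch(by, district = "district_id", province = "province",
                  year = "year", season = "season")
    vals <- c(as.character(observed_events[[col]]),
              unlist(lapply(future_events, function(e) as.character(e[[col]]))))
    levels <- if (by == "season") austral_seasons() else sort(unique(vals))
  }
  obs <- summarise_events(observed_events, by = by, levels = levels)
  rows <- lapply(names(future_events), function(sc) {
    fut <- summarise_events(future_events[[sc]], by = by, levels = levels)
    ev <- pct_change(obs$n_events, fut$n_events)
    dd <- pct_change(obs$event_days, fut$event_days)
    tibble::tibble(
      scenario = sc,
      group = rep(obs$group, 2),
      measure = rep(c("events", "event_days"), each = nrow(obs)),
      observed = c(ev$observed, dd$observed),
      future = c(ev$future, dd$future),
      pct_raw = c(ev$pct_raw, dd$pct_raw),
      pct_rounded = c(ev$pct_rounded, dd$pct_rounded)
    )
  })
  dplyr::bind_rows(rows)
}
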