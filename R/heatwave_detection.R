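#' Heatwave detection configuration
#'
#' The study definition of a heatwave: DTR exceedance of a national
#' health-based threshold (default 12.8 degrees C) for at least
#' `min_duration` consecutive days (default 2), counting only days whose
#' mean temperature is at or above the district MMT. Exceedance is strict
#' by default (`dtr > threshold`); printed counts cannot adjudicate strict
#' vs inclusive, so the convention is switchable. `max_gap` controls
#' gap-joining across non-qualifying days; the study definition is a plain
#' consecutive-day exceedance, so the default is 0 (a single non-qualifying
#' or missing day always terminates an event).
#'
#' @param dtr_threshold DTR threshold in degrees C; must be positive.
#' @param min_duration minimum event length in days; must be >= 1.
#' @param strict_exceedance logical; `>` (default) vs `>=`.
#' @param max_gap maximum run of non-qualifying days bridged inside an
#'   event; default 0 (no gap-joining).
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(dtr_threshold = 12.8, min_duration = 2,
                             strict_exceedance = TRUE, max_gap = 0) {
  stopifnot(is.finite(dtr_threshold), dtr_threshold > 0,
            min_duration >= 1, max_gap >= 0)
  structure(list(dtr_threshold = dtr_threshold,
                 min_duration = as.integer(min_duration),
                 strict_exceedance = isTRUE(strict_exceedance),
                 max_gap = as.integer(max_gap)),
            class = "threshold_config")
}

#' Which days qualify for heatwave analysis?
#'
#' A day qualifies iff DTR and mean temperature are both present, DTR exceeds
#' the threshold (per the configured convention), and the mean temperature is
#' at or above the district MMT. MMT masking is applied per day, before run
#' detection: days below MMT are excluded from the analysis outright.
#' Missing-data days never qualify.
#'
#' @param derived derived tibble from [derive_daily()].
#' @param mmt district minimum mortality temperature in degrees C; use
#'   `-Inf` to disable MMT masking.
#' @param config a [threshold_config()].
#' @return logical vector, one element per day, no `NA`.
#' @export
qualify_days <- function(derived, mmt = -Inf, config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  dtr <- derived$dtr
  tmean <- derived$tmean
  exceeds <- if (config$strict_exceedance) dtr > config$dtr_threshold else dtr >= config$dtr_threshold
  q <- !is.na(dtr) & !is.na(tmean) & exceeds & tmean >= mmt
  q[is.na(q)] <- FALSE
  q
}

#' Detect heatwave events in one district series
#'
#' Events are exactly the maximal runs of qualifying days (see
#' [qualify_days()]) of length at least `min_duration`. Shorter runs produce
#' no event; with the default `max_gap = 0` a single non-qualifying day —
#' including a missing-data day — terminates a run. Events are returned
#' sorted by start date and are non-overlapping. The peak is the event day
#' of maximum DTR, the detection metric (earliest such day on ties); the day
#' of maximum tmax is also reported as an auxiliary field.
#'
#' @param derived a [daily_series()] or derived tibble from [derive_daily()];
#'   must sit on a contiguous daily calendar.
#' @param meta one-row district metadata (tibble or list with at least
#'   `mmt`; optionally `district_id`, `province`), or `NULL` to detect with
#'   no MMT masking.
#' @param config a [threshold_config()].
#' @return tibble of events: `district_id`, `start`, `end`, `peak_date`,
#'   `peak_tmax_date`, `duration`, `peak_dtr`, `mean_dtr`,
#'   `cumulative_exceedance` (degree-days above threshold), `season`
#'   (austral season of the start date), `year` (year of the start date).
#' @export
detect_events <- function(derived, meta = NULL, config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  if (!"dtr" %in% names(derived)) derived <- derive_daily(derived)
  if (nrow(derived) == 0) return(empty_events())
  if (nrow(derived) > 1 && any(diff(derived$date) != 1)) {
    stop("detect_events requires a contiguous daily calendar", call. = FALSE)
  }
  mmt <- if (is.null(meta)) -Inf else meta$mmt
  did <- if (!is.null(meta) && !is.null(meta$district_id)) {
    as.character(meta$district_id)
  } else if (!is.null(attr(derived, "district_id"))) {
    attr(derived, "district_id")
  } else {
    as.character(derived$district_id[1])
  }
  q <- qualify_days(derived, mmt = mmt, config = config)
  if (config$max_gap > 0) q <- bridge_gaps(q, config$max_gap)
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$min_duration
  if (!any(keep)) return(empty_events())
  events <- lapply(which(keep), function(k) {
    i <- starts[k]:ends[k]
    dtr <- derived$dtr[i]
    # bridged days inside an event (max_gap > 0) may have missing dtr
    exc <- sum(dtr - config$dtr_threshold, na.rm = TRUE)
    peak_i <- i[which.max(dtr)]
    peak_tmax_i <- i[which.max(derived$tmax[i])]
    tibble::tibble(
      district_id = did,
      start = derived$date[starts[k]],
      end = derived$date[ends[k]],
      peak_date = derived$date[peak_i],
      peak_tmax_date = derived$date[peak_tmax_i],
      duration = inclusive_day_count(derived$date[starts[k]], derived$date[ends[k]]),
      peak_dtr = max(dtr, na.rm = TRUE),
      mean_dtr = mean(dtr, na.rm = TRUE),
      cumulative_exceedance = exc
    )
  })
  out <- dplyr::bind_rows(events)
  out$season <- season_of(out$start)
  out$year <- as.integer(format(out$start, "%Y"))
  out
}

bridge_gaps <- function(q, max_gap) {
  r <- rle(q)
  n <- length(r$values)
  # a FALSE run is bridged when short enough and flanked by TRUE runs
  for (k in seq_len(n)) {
    if (!r$values[k] && r$lengths[k] <= max_gap && k > 1 && k < n) {
      r$values[k] <- TRUE
    }
  }
  inverse.rle(r)
}

#' Zero-row event table with the canonical columns
#' @keywords internal
empty_events <- function() {
  tibble::tibble(
    district_id = character(),
    start = as.Date(character()),
    end = as.Date(character()),
    peak_date = as.Date(character()),
    peak_tmax_date = as.Date(character()),
    duration = integer(),
    peak_dtr = numeric(),
    mean_dtr = numeric(),
    cumulative_exceedance = numeric(),
    season = factor(character(), levels = austral_seasons()),
    year = integer()
  )
}

#' Detect events across a collection of district series
#'
#' @param series_list named list of [daily_series()].
#' @param meta metadata tibble (one row per district); `NULL` disables MMT
#'   masking everywhere.
#' @param config a [threshold_config()].
#' @return combined event tibble (see [detect_events()]), with `province`
#'   joined in when metadata are supplied.
#' @export
detect_events_all <- function(series_list, meta = NULL, config = threshold_config()) {
  ev <- lapply(names(series_list), function(id) {
    m <- if (is.null(meta)) NULL else meta[meta$district_id == id, ]
    if (!is.null(m) && nrow(m) == 0) {
      stop(sprintf("district %s not in metadata", id), call. = FALSE)
    }
    detect_events(derive_daily(series_list[[id]]), meta = m, config = config)
  })
  out <- dplyr::bind_rows(ev)
  if (nrow(out) == 0) out <- empty_events()
  if (!is.null(meta)) {
    out <- dplyr::left_join(out, meta[, c("district_id", "province")],
                            by = "district_id")
  }
  out
}

#' Inclusive duration of one event
#'
#' The printed worked example: an event running 29 October 2015 to
#' 13 January 2016 lasts 77 days.
#'
#' @inheritParams inclusive_day_count
#' @return integer day count.
#' @export
event_duration <- function(start, end) inclusive_day_count(start, end)

#' Summarise detected events by district, province, year or season
#'
#' Per-group event count, total event-days, maximum duration and maximum
#' peak DTR. Groups with zero events appear with zero counts, zero
#' event-days and zero max duration (max peak DTR is `NA`: there is no
#' temperature to report).
#'
#' @param events event tibble from [detect_events()] / [detect_events_all()].
#' @param by grouping key: `"district"`, `"province"`, `"year"` or
#'   `"season"`.
#' @param levels optional vector of group values to zero-fill (e.g. all
#'   district ids, or a full year range); defaults to the values observed in
#'   `events` (plus all four seasons when `by = "season"`).
#' @return tibble (`group`, `n_events`, `event_days`, `max_duration`,
#'   `max_peak_dtr`).
#' @export
summarise_events <- function(events, by = c("district", "province", "year", "season"),
                             levels = NULL) {
  by <- match.arg(by)
  col <- switch(by, district = "district_id", province = "province",
                year = "year", season = "season")
  if (!col %in% names(events)) {
    stop(sprintf("events table has no '%s' column (join metadata first?)", col),
         call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- if (by == "season") austral_seasons() else sort(unique(events[[col]]))
  }
  agg <- if (nrow(events) == 0) {
    tibble::tibble(group = character(), n_events = integer(),
                   event_days = integer(), max_duration = integer(),
                   max_peak_dtr = numeric())
  } else {
    dplyr::summarise(
      dplyr::group_by(events, group = as.character(.data[[col]])),
      n_events = dplyr::n(),
      event_days = sum(.data$duration),
      max_duration = max(.data$duration),
      max_peak_dtr = max(.data$peak_dtr),
      .groups = "drop"
    )
  }
  out <- dplyr::left_join(tibble::tibble(group = as.character(levels)), agg,
                          by = "group")
  out$n_events[is.na(out$n_events)] <- 0L
  out$event_days[is.na(out$event_days)] <- 0L
  out$max_duration[is.na(out$max_duration)] <- 0L
  out
}
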