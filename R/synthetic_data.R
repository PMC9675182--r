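#' District climate regime for the synthetic generator
#'
#' Parameters of one district's synthetic daily temperature process: annual
#' mean levels, seasonal amplitudes (southern-hemisphere phase, peak in
#' mid-January), a baseline diurnal temperature range, AR(1)-persistent
#' day-to-day noise, and the district's MMT. Coastal regimes default to a
#' lower `dtr_base` than inland ones, emulating the continentality contrast
#' in the study region (coastal mean DTR roughly 8-11.5 degrees C, inland up
#' to about 19.4).
#'
#' @param district_id,province,coastal identity fields.
#' @param tmax_mean_annual annual mean daily maximum, degrees C.
#' @param dtr_base baseline mean DTR, degrees C (> 0).
#' @param tmin_mean_annual annual mean daily minimum; defaults to
#'   `tmax_mean_annual - dtr_base`.
#' @param seasonal_amplitude_tmax,seasonal_amplitude_tmin seasonal
#'   half-ranges, degrees C.
#' @param noise_sd stationary standard deviation of the AR(1) noise,
#'   degrees C (>= 0).
#' @param ar1_coeff lag-1 autocorrelation in (-1, 1); default 0.7 — heatwaves
#'   are multi-day persistent phenomena, and i.i.d. noise would make runs of
#'   two or more hot days unrealistically rare.
#' @param mmt district minimum mortality temperature, degrees C.
#' @param lat,lon centroid coordinates, decimal degrees.
#' @param peak_doy day of year of the seasonal peak; default 15 (austral
#'   mid-summer).
#' @return a `district_regime` list.
#' @export
district_regime <- function(district_id, province, coastal,
                            tmax_mean_annual, dtr_base,
                            tmin_mean_annual = tmax_mean_annual - dtr_base,
                            seasonal_amplitude_tmax = 5,
                            seasonal_amplitude_tmin = 4.5,
                            noise_sd = 2, ar1_coeff = 0.7,
                            mmt = 22, lat = -29, lon = 25, peak_doy = 15) {
  stopifnot(dtr_base > 0, noise_sd >= 0, abs(ar1_coeff) < 1,
            seasonal_amplitude_tmax >= 0, seasonal_amplitude_tmin >= 0)
  structure(list(district_id = as.character(district_id),
                 province = as.character(province),
                 coastal = isTRUE(coastal),
                 tmax_mean_annual = tmax_mean_annual,
                 tmin_mean_annual = tmin_mean_annual,
                 seasonal_amplitude_tmax = seasonal_amplitude_tmax,
                 seasonal_amplitude_tmin = seasonal_amplitude_tmin,
                 dtr_base = dtr_base, noise_sd = noise_sd,
                 ar1_coeff = ar1_coeff, mmt = mmt,
                 lat = lat, lon = lon, peak_doy = peak_doy),
            class = "district_regime")
}

#' Default test-scale regimes: 3 coastal + 3 inland districts
#'
#' Six districts keep the suite fast while preserving the coastal/inland DTR
#' contrast; [full_scale_regimes()] reproduces the 50-district shape.
#'
#' @return named list of [district_regime()].
#' @export
default_regimes <- function() {
  regs <- list(
    district_regime("C01", "West Coast", TRUE, tmax_mean_annual = 23.0,
                    dtr_base = 10.5, seasonal_amplitude_tmax = 4.5,
                    seasonal_amplitude_tmin = 4.0, noise_sd = 2.0,
                    mmt = 20.5, lat = -33.9, lon = 18.6),
    district_regime("C02", "South Coast", TRUE, tmax_mean_annual = 24.0,
                    dtr_base = 11.0, seasonal_amplitude_tmax = 4.0,
                    seasonal_amplitude_tmin = 3.6, noise_sd = 2.0,
                    mmt = 21.0, lat = -33.0, lon = 27.9),
    district_regime("C03", "East Coast", TRUE, tmax_mean_annual = 25.5,
                    dtr_base = 9.5, seasonal_amplitude_tmax = 3.5,
                    seasonal_amplitude_tmin = 3.2, noise_sd = 1.8,
                    mmt = 22.0, lat = -29.9, lon = 31.0),
    district_regime("I01", "Northern Interior", FALSE, tmax_mean_annual = 29.0,
                    dtr_base = 17.5, seasonal_amplitude_tmax = 6.0,
                    seasonal_amplitude_tmin = 5.0, noise_sd = 2.5,
                    mmt = 24.0, lat = -25.6, lon = 27.1),
    district_regime("I02", "Central Plateau", FALSE, tmax_mean_annual = 27.0,
                    dtr_base = 18.0, seasonal_amplitude_tmax = 6.0,
                    seasonal_amplitude_tmin = 5.2, noise_sd = 2.5,
                    mmt = 23.0, lat = -29.1, lon = 26.2),
    district_regime("I03", "Arid West", FALSE, tmax_mean_annual = 29.5,
                    dtr_base = 16.5, seasonal_amplitude_tmax = 6.5,
                    seasonal_amplitude_tmin = 5.5, noise_sd = 2.5,
                    mmt = 24.5, lat = -28.7, lon = 24.7)
  )
  stats::setNames(regs, vapply(regs, `[[`, character(1), "district_id"))
}

#' Full-scale regime profile: 50 districts (20 coastal, 30 inland)
#'
#' Deterministic parameter spreads around the defaults, reproducing the
#' 50-district shape of the study region without any random draw.
#'
#' @return named list of [district_regime()].
#' @export
full_scale_regimes <- function() {
  coastal <- lapply(seq_len(20), function(i) {
    district_regime(sprintf("C%02d", i),
                    province = paste("Coastal Province", (i - 1) %/% 7 + 1),
                    coastal = TRUE,
                    tmax_mean_annual = 22.5 + 0.15 * i,
                    dtr_base = 8.5 + 0.15 * i,
                    seasonal_amplitude_tmax = 3.5 + 0.05 * i,
                    seasonal_amplitude_tmin = 3.2 + 0.04 * i,
                    noise_sd = 2.0, mmt = 20 + 0.1 * i,
                    lat = -34.2 + 0.25 * i, lon = 18.5 + 0.6 * i)
  })
  inland <- lapply(seq_len(30), function(i) {
    district_regime(sprintf("I%02d", i),
                    province = paste("Inland Province", (i - 1) %/% 10 + 1),
                    coastal = FALSE,
                    tmax_mean_annual = 26.5 + 0.1 * i,
                    dtr_base = 15.0 + 0.14 * i,
                    seasonal_amplitude_tmax = 5.5 + 0.03 * i,
                    seasonal_amplitude_tmin = 4.8 + 0.02 * i,
                    noise_sd = 2.5, mmt = 22.5 + 0.08 * i,
                    lat = -30.5 + 0.2 * i, lon = 22.0 + 0.3 * i)
  })
  regs <- c(coastal, inland)
  stats::setNames(regs, vapply(regs, `[[`, character(1), "district_id"))
}

#' Metadata tibble for a set of regimes
#'
#' @param regimes named list of [district_regime()].
#' @return metadata tibble as produced by [read_district_meta()].
#' @export
synthetic_meta <- function(regimes = default_regimes()) {
  validate_district_meta(tibble::tibble(
    district_id = vapply(regimes, `[[`, character(1), "district_id"),
    province = vapply(regimes, `[[`, character(1), "province"),
    mmt = vapply(regimes, `[[`, numeric(1), "mmt"),
    lat = vapply(regimes, `[[`, numeric(1), "lat"),
    lon = vapply(regimes, `[[`, numeric(1), "lon"),
    coastal = vapply(regimes, `[[`, logical(1), "coastal")
  ))
}

ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  init <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive", init = init))
}

#' Generate one district's synthetic daily series
#'
#' Daily minimum temperature follows a seasonal cosine (peak at `peak_doy`,
#' southern-hemisphere phase) plus stationary AR(1) noise; DTR follows its
#' own seasonal term (`dtr_base` plus the amplitude difference times the
#' same cosine) plus independent AR(1) noise, floored at 0.2 degrees C; and
#' `tmax = tmin + dtr`. This construction keeps the mean DTR at `dtr_base`,
#' shares the seasonal phase between the two variables, and makes
#' `tmax >= tmin` structural rather than enforced by post-hoc censoring.
#' With `noise_sd = 0` and equal amplitudes the series is the deterministic
#' seasonal curve with constant DTR equal to `dtr_base`.
#'
#' @param regime a [district_regime()].
#' @param period length-2 vector (start, end).
#' @param seed integer seed; a fixed seed reproduces the series exactly.
#' @return a [daily_series()].
#' @export
generate_series <- function(regime, period = c("2014-01-01", "2019-12-31"),
                            seed = NULL) {
  stopifnot(inherits(regime, "district_regime"))
  dates <- date_seq(period[1], period[2])
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cos(2 * pi * (doy - regime$peak_doy) / 365.25)
  gen <- function() {
    tmin <- regime$tmin_mean_annual +
      regime$seasonal_amplitude_tmin * seasonal +
      ar1_noise(n, regime$noise_sd, regime$ar1_coeff)
    amp_diff <- regime$seasonal_amplitude_tmax - regime$seasonal_amplitude_tmin
    dtr <- pmax(0.2, regime$dtr_base + amp_diff * seasonal +
                  ar1_noise(n, regime$noise_sd, regime$ar1_coeff))
    daily_series(regime$district_id, dates, tmax = tmin + dtr, tmin = tmin,
                 period_start = dates[1], period_end = dates[n])
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate series for every regime in a set
#'
#' Seeds are derived deterministically from `seed` per district so each
#' district's series is independent yet the whole dataset is reproducible.
#'
#' @param regimes named list of [district_regime()].
#' @param period length-2 vector (start, end).
#' @param seed integer master seed.
#' @return named list of [daily_series()].
#' @export
generate_all_series <- function(regimes, period = c("2014-01-01", "2019-12-31"),
                                seed = 1) {
  out <- lapply(seq_along(regimes), function(k) {
    sub_seed <- as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
    generate_series(regimes[[k]], period, seed = sub_seed)
  })
  stats::setNames(out, names(regimes))
}

#' Inject missing days into a series
#'
#' Each day is independently set fully missing (both temperatures) with
#' probability `rate`, emulating station outages at the study's aggregate
#' missingness (16% of days). Block missingness for stress tests: set
#' `block_length > 1` to drop contiguous runs instead, at the same expected
#' rate. The realised missing fraction is attached as attribute
#' `realised_missing_rate`.
#'
#' @param series a [daily_series()].
#' @param rate target missingness fraction in [0, 1).
#' @param seed integer seed.
#' @param block_length mean length of missing blocks; 1 = i.i.d. days.
#' @return the masked [daily_series()].
#' @export
inject_missingness <- function(series, rate = 0.16, seed = NULL, block_length = 1) {
  stopifnot(rate >= 0)
  if (rate >= 1) stop("missingness rate must be < 1", call. = FALSE)
  n <- nrow(series)
  draw <- function() {
    if (block_length <= 1) {
      stats::runif(n) < rate
    } else {
      starts <- stats::runif(n) < rate / block_length
      mask <- rep(FALSE, n)
      for (s in which(starts)) {
        mask[s:min(n, s + block_length - 1L)] <- TRUE
      }
      mask
    }
  }
  mask <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- series
  out$tmax[mask] <- NA_real_
  out$tmin[mask] <- NA_real_
  attr(out, "realised_missing_rate") <- mean(mask)
  out
}

#' Plant ground-truth heatwave events into a series
#'
#' On each planted day, DTR is set above the detection threshold with a
#' triangular intensity profile (unique interior peak on odd lengths, the
#' earlier of the middle pair on even lengths) and tmin is raised just enough
#' that the day's mean temperature clears `mmt`. The day immediately before
#' and after each planted window is depressed below threshold, so planted
#' boundaries are exactly recoverable by detection when the background does
#' not itself qualify. Planted windows must not overlap or touch (adjacent
#' windows would merge into one run and become unrecoverable); a one-day gap
#' is allowed.
#'
#' @param series a [daily_series()].
#' @param events tibble with columns `start`, `end` and optionally `boost`
#'   (degrees C of DTR above threshold at the shoulders; default 1.5).
#' @param config a [threshold_config()].
#' @param mmt the district MMT used for masking downstream (`-Inf` to
#'   ignore).
#' @return the modified [daily_series()] with attribute `planted`: a tibble
#'   of the ground truth (`district_id`, `start`, `end`, `peak_date`,
#'   `duration`).
#' @export
plant_events <- function(series, events, config = threshold_config(), mmt = -Inf) {
  stopifnot(inherits(series, "daily_series"))
  if (is.null(events) || nrow(events) == 0) {
    attr(series, "planted") <- tibble::tibble(
      district_id = character(), start = as.Date(character()),
      end = as.Date(character()), peak_date = as.Date(character()),
      duration = integer())
    return(series)
  }
  ev <- tibble::tibble(start = as_civil_date(events$start),
                       end = as_civil_date(events$end),
                       boost = if ("boost" %in% names(events)) events$boost else 1.5)
  if (any(ev$end < ev$start)) stop("event end before start", call. = FALSE)
  if (any(ev$boost <= 0)) stop("boost must be positive", call. = FALSE)
  ps <- attr(series, "period_start")
  pe <- attr(series, "period_end")
  if (any(ev$start < ps | ev$end > pe)) {
    stop("planted event outside the series period", call. = FALSE)
  }
  ev <- ev[order(ev$start), ]
  if (nrow(ev) > 1) {
    gap <- as.integer(ev$start[-1] - ev$end[-nrow(ev)])
    if (any(gap < 1)) stop("planted events overlap", call. = FALSE)
    if (any(gap == 1)) {
      stop("planted events are adjacent and would merge; leave at least a one-day gap",
           call. = FALSE)
    }
  }
  out <- series
  thr <- config$dtr_threshold
  truth <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    i <- match(date_seq(ev$start[k], ev$end[k]), out$date)
    len <- length(i)
    pos <- pmin(seq_len(len), rev(seq_len(len)))
    # strictly decreasing tail-breaker: the peak day is unique even after
    # float round-trip through tmax = tmin + dtr
    dtr_k <- thr + ev$boost[k] + 0.1 * pos - 0.001 * (seq_len(len) - 1)
    tmin_k <- out$tmin[i]
    tmin_k[is.na(tmin_k)] <- if (is.finite(mmt)) mmt else 15
    if (is.finite(mmt)) tmin_k <- pmax(tmin_k, mmt + 0.5 - dtr_k / 2)
    out$tmin[i] <- tmin_k
    out$tmax[i] <- tmin_k + dtr_k
    peak_idx <- which.max(dtr_k)
    truth[[k]] <- tibble::tibble(
      district_id = attr(series, "district_id"),
      start = ev$start[k], end = ev$end[k],
      peak_date = out$date[i[peak_idx]],
      duration = len
    )
    for (g in c(ev$start[k] - 1, ev$end[k] + 1)) {
      j <- match(g, out$date)
      if (!is.na(j) && !is.na(out$tmax[j]) && !is.na(out$tmin[j]) &&
          out$tmax[j] - out$tmin[j] >= thr - 0.5) {
        out$tmax[j] <- out$tmin[j] + thr - 1
      }
    }
  }
  attr(out, "planted") <- dplyr::bind_rows(truth)
  out
}

#' Noiseless multi-district fixture with planted ground truth
#'
#' Builds sub-threshold, noise-free regimes (equal seasonal amplitudes, DTR
#' base capped below the detection threshold, so no background day ever
#' qualifies), plants non-overlapping random events in each district, and
#' returns the dataset together with its exact ground truth. Every planted
#' event is recoverable by [detect_events()] with the same config: count,
#' boundaries and peak days match exactly.
#'
#' @param regimes base regimes; defaults to [default_regimes()].
#' @param period length-2 vector (start, end).
#' @param events_per_district events planted per district.
#' @param seed integer seed for event placement.
#' @param config a [threshold_config()].
#' @param max_duration longest planted duration in days.
#' @return list with `series` (named list), `truth` (event tibble), `meta`
#'   (metadata tibble) and `regimes` (the flattened regimes used).
#' @export
planted_fixture <- function(regimes = default_regimes(),
                            period = c("2014-01-01", "2019-12-31"),
                            events_per_district = 3, seed = 1,
                            config = threshold_config(), max_duration = 12) {
  flat <- lapply(regimes, function(r) {
    r$noise_sd <- 0
    r$seasonal_amplitude_tmin <- r$seasonal_amplitude_tmax
    r$dtr_base <- min(r$dtr_base, config$dtr_threshold - 1.5)
    r
  })
  meta <- synthetic_meta(flat)
  n_days <- inclusive_day_count(period[1], period[2])
  p_start <- as_civil_date(period[1])
  place <- function() {
    lapply(names(flat), function(id) {
      s <- generate_series(flat[[id]], period)
      taken <- rep(FALSE, n_days)
      wins <- list()
      while (length(wins) < events_per_district) {
        len <- sample(config$min_duration:max_duration, 1)
        st <- sample(1:(n_days - len - 1), 1)
        span <- max(1, st - 2):min(n_days, st + len + 1)
        if (any(taken[span])) next
        taken[st:(st + len - 1)] <- TRUE
        wins[[length(wins) + 1]] <- tibble::tibble(
          start = p_start + st - 1, end = p_start + st + len - 2)
      }
      plant_events(s, dplyr::bind_rows(wins), config = config,
                   mmt = flat[[id]]$mmt)
    })
  }
  series <- withr::with_seed(seed, place())
  names(series) <- names(flat)
  truth <- dplyr::bind_rows(lapply(series, attr, "planted"))
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(district_id = character(),
                            start = as.Date(character()),
                            end = as.Date(character()),
                            peak_date = as.Date(character()),
                            duration = integer())
  }
  truth <- truth[order(truth$district_id, truth$start), ]
  list(series = series, truth = truth, meta = meta, regimes = flat)
}

#' Generate a per-district scenario anomaly field
#'
#' Deltas are the base values plus optional smooth spatial variation (a
#' deterministic function of the district centroid scaled by `spatial_sd`)
#' plus optional seeded jitter. With `monthly = TRUE` the deltas are emitted
#' per calendar month (identical across months unless jittered), exercising
#' the monthly-broadcast path.
#'
#' @param scenario scenario label.
#' @param base_delta_tmax,base_delta_tmin base deltas, degrees C.
#' @param meta district metadata tibble.
#' @param spatial_sd scale of smooth spatial variation, degrees C.
#' @param monthly emit per-month rows instead of year-round rows.
#' @param seed optional seed for jitter (only used when `spatial_sd > 0`).
#' @return an [anomaly_field()].
#' @export
generate_anomaly <- function(scenario, base_delta_tmax, base_delta_tmin,
                             meta, spatial_sd = 0, monthly = FALSE,
                             seed = NULL) {
  stopifnot(is.finite(base_delta_tmax), is.finite(base_delta_tmin))
  spatial <- if (spatial_sd > 0) {
    spatial_sd * sin(meta$lat * pi / 30) * cos(meta$lon * pi / 40)
  } else {
    rep(0, nrow(meta))
  }
  months <- if (monthly) 1:12 else NA_integer_
  grid_df <- expand.grid(district_id = meta$district_id, month = months,
                         stringsAsFactors = FALSE)
  sp <- spatial[match(grid_df$district_id, meta$district_id)]
  anomaly_field(scenario, tibble::tibble(
    variable = rep(c("tmax", "tmin"), each = nrow(grid_df)),
    district_id = rep(grid_df$district_id, 2),
    month = rep(grid_df$month, 2),
    delta = c(base_delta_tmax + sp, base_delta_tmin + sp)
  ))
}

#' Generate a gridded anomaly field
#'
#' A regular lat/lon grid of deltas: base value plus a smooth separable
#' sinusoidal pattern of amplitude `spatial_amp` (zero by default, giving a
#' uniform field).
#'
#' @param base_delta base delta, degrees C.
#' @param lats,lons strictly increasing grid coordinates.
#' @param spatial_amp amplitude of the smooth spatial pattern, degrees C.
#' @return grid list (`lats`, `lons`, `values`) for
#'   [bilinear_interpolate()].
#' @export
generate_anomaly_grid <- function(base_delta, lats, lons, spatial_amp = 0) {
  values <- base_delta + spatial_amp *
    outer(sin(lats * pi / 30), cos(lons * pi / 40))
  list(lats = lats, lons = lons, values = values)
}
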