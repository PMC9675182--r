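#' Per-day derived temperature quantities
#'
#' Adds the diurnal temperature range `dtr = tmax - tmin` (the exposure
#' metric whose exceedance defines a hot day) and the daily mean temperature
#' `tmean = (tmax + tmin) / 2` (the midrange — the only mean computable from
#' daily max/min alone; it is what MMT masking is applied to). Missingness
#' propagates: `dtr` and `tmean` are `NA` whenever either input is.
#'
#' @param series a [daily_series()].
#' @return tibble with columns `district_id`, `date`, `tmax`, `tmin`, `dtr`,
#'   `tmean`.
#' @export
derive_daily <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  out <- tibble::as_tibble(as.data.frame(series))
  out$dtr <- out$tmax - out$tmin
  out$tmean <- (out$tmax + out$tmin) / 2
  attr(out, "district_id") <- attr(series, "district_id")
  attr(out, "period_start") <- attr(series, "period_start")
  attr(out, "period_end") <- attr(series, "period_end")
  out
}

#' Descriptive statistics for one temperature variable
#'
#' Mean, sample standard deviation (n - 1 denominator) and 95th percentile
#' over non-missing days only, in the layout of a per-district descriptive
#' table (one row per variable). The percentile uses linear interpolation
#' between the closest order statistics (`stats::quantile` type 7);
#' alternative quantile definitions can be selected via `quantile_type`.
#'
#' @param series a [daily_series()] or derived tibble from [derive_daily()].
#' @param variable one of `"tmax"`, `"tmin"`, `"dtr"`, `"tmean"`.
#' @param quantile_type passed to [stats::quantile()]; default 7.
#' @return tibble with columns `variable`, `mean`, `sd`, `p95`, `n`.
#' @export
descriptive_stats <- function(series, variable = c("tmax", "tmin", "dtr", "tmean"),
                              quantile_type = 7) {
  variable <- match.arg(variable)
  d <- if (variable %in% c("dtr", "tmean") && !variable %in% names(series)) {
    derive_daily(series)
  } else {
    series
  }
  x <- d[[variable]]
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop("descriptive_stats needs at least 2 non-missing values", call. = FALSE)
  }
  tibble::tibble(
    variable = variable,
    mean = mean(x),
    sd = stats::sd(x),
    p95 = unname(stats::quantile(x, 0.95, type = quantile_type)),
    n = length(x)
  )
}

#' Table of descriptive statistics for several districts
#'
#' Convenience wrapper reproducing the structure of a per-district
#' descriptive table: one row per (district, variable).
#'
#' @param series_list named list of [daily_series()].
#' @param meta optional metadata tibble; adds a `province` column.
#' @param variables variables to summarise.
#' @inheritParams descriptive_stats
#' @return tibble (`district_id`, [`province`,] `variable`, `mean`, `sd`,
#'   `p95`, `n`).
#' @export
descriptive_table <- function(series_list, meta = NULL,
                              variables = c("tmax", "tmin", "dtr"),
                              quantile_type = 7) {
  rows <- lapply(names(series_list), function(id) {
    d <- derive_daily(series_list[[id]])
    out <- dplyr::bind_rows(lapply(variables, function(v) {
      descriptive_stats(d, v, quantile_type = quantile_type)
    }))
    out$district_id <- id
    out
  })
  tab <- dplyr::bind_rows(rows)
  tab <- tab[, c("district_id", "variable", "mean", "sd", "p95", "n")]
  if (!is.null(meta)) {
    tab <- dplyr::left_join(tab, meta[, c("district_id", "province")],
                            by = "district_id")
    tab <- tab[, c("district_id", "province", "variable", "mean", "sd", "p95", "n")]
  }
  tab
}

#' Count hot days (DTR above threshold)
#'
#' A hot day is a day whose DTR exceeds the national health-based threshold
#' (default 12.8 degrees C, the level above which all-cause mortality rises).
#' Exceedance is strict (`dtr > threshold`) by default; set `strict = FALSE`
#' for `>=`. Days with missing DTR are never counted.
#'
#' @param derived derived tibble from [derive_daily()] (or anything with a
#'   `dtr` column), or a [daily_series()].
#' @param threshold DTR threshold in degrees C.
#' @param strict logical; strict (`>`) vs inclusive (`>=`) exceedance.
#' @return integer count of hot days.
#' @export
count_hot_days <- function(derived, threshold = 12.8, strict = TRUE) {
  stopifnot(is.finite(threshold))
  if (!"dtr" %in% names(derived)) derived <- derive_daily(derived)
  dtr <- derived$dtr
  hit <- if (strict) dtr > threshold else dtr >= threshold
  sum(hit, na.rm = TRUE)
}

#' Hot-day counts for several districts
#'
#' @param series_list named list of [daily_series()].
#' @inheritParams count_hot_days
#' @return tibble (`district_id`, `n_hot_days`, `n_days`, `pct_of_period`).
#' @export
hot_day_table <- function(series_list, threshold = 12.8, strict = TRUE) {
  tibble::tibble(
    district_id = names(series_list),
    n_hot_days = vapply(series_list, count_hot_days, integer(1),
                        threshold = threshold, strict = strict),
    n_days = vapply(series_list, nrow, integer(1))
  ) |>
    dplyr::mutate(pct_of_period = 100 * .data$n_hot_days / .data$n_days)
}
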