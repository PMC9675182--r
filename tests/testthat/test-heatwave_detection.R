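test_that("day qualification requires DTR exceedance and mean temperature at or above MMT", {
  d <- derive_daily(toy_series(c(13, 13, NA), tmean = c(25, 18, 25)))
  cfg <- threshold_config()
  expect_equal(qualify_days(d, mmt = 20, cfg), c(TRUE, FALSE, FALSE))
  # dtr exactly at threshold: strict excludes, inclusive admits
  d2 <- derive_daily(daily_series("T1", "2015-01-01", tmax = 12.8, tmin = 0))
  expect_false(qualify_days(d2, mmt = -Inf, threshold_config())[1])
  expect_true(qualify_days(d2, mmt = -Inf,
                           threshold_config(strict_exceedance = FALSE))[1])
})

test_that("a three-day exceedance run yields one event with hand-computed metrics", {
  d <- derive_daily(toy_series(c(10, 13, 14, 13.5, 10), tmean = 25))
  ev <- detect_events(d, meta = list(mmt = -Inf, district_id = "T1"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 3L)
  expect_equal(ev$start, as.Date("2015-01-02"))
  expect_equal(ev$end, as.Date("2015-01-04"))
  expect_equal(ev$peak_date, as.Date("2015-01-03"))
  expect_equal(ev$peak_dtr, 14)
  expect_equal(ev$mean_dtr, 13.5)
  expect_equal(ev$cumulative_exceedance, 0.2 + 1.2 + 0.7, tolerance = 1e-9)
  expect_equal(as.character(ev$season), "summer")
  expect_equal(ev$year, 2015L)
})

test_that("runs below the minimum duration produce no event; gaps split events", {
  one <- derive_daily(toy_series(c(10, 14, 10), tmean = 25))
  expect_equal(nrow(detect_events(one)), 0)

  qqnqq <- derive_daily(toy_series(c(14, 14, 10, 14, 14), tmean = 25))
  ev <- detect_events(qqnqq)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$duration, c(2L, 2L))
  expect_true(all(ev$start[-1] > ev$end[-nrow(ev)])) # sorted, non-overlapping

  # a missing day terminates a run just like a non-qualifying one
  gap <- derive_daily(toy_series(c(14, 14, NA, 14, 14), tmean = 25))
  expect_equal(nrow(detect_events(gap)), 2)

  # optional gap-joining bridges a single bad day into one event
  cfg <- threshold_config(max_gap = 1)
  ev1 <- detect_events(qqnqq, config = cfg)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$duration, 5L)
})

test_that("peak ties resolve to the earliest day", {
  d <- derive_daily(toy_series(c(14, 15, 15, 14), tmean = 25))
  ev <- detect_events(d)
  expect_equal(ev$peak_date, as.Date("2015-01-02"))
})

test_that("detection requires a contiguous daily calendar", {
  d <- derive_daily(toy_series(c(14, 14, 14), tmean = 25))
  broken <- d[-2, ]
  expect_error(detect_events(broken), "contiguous")
})

test_that("detection matches brute-force maximal-run enumeration on random sequences", {
  withr::with_seed(101, {
    for (k in 1:300) {
      n <- sample(2:400, 1)
      p <- runif(1, 0.1, 0.9)
      q <- runif(n) < p
      min_dur <- sample(1:3, 1)
      dtr <- ifelse(q, 15, 10)
      d <- derive_daily(toy_series(dtr, tmean = 25))
      ev <- detect_events(d, config = threshold_config(min_duration = min_dur))
      runs <- oracle_runs(q, min_dur)
      expect_equal(nrow(ev), length(runs))
      if (length(runs) > 0) {
        expect_equal(as.integer(ev$start - d$date[1]) + 1L,
                     vapply(runs, `[`, integer(1), 1))
        expect_equal(as.integer(ev$end - d$date[1]) + 1L,
                     vapply(runs, `[`, integer(1), 2))
      }
    }
  })
})

test_that("event days satisfy the qualification predicate and durations conserve", {
  s <- generate_series(default_regimes()$I03, seed = 21)
  s <- inject_missingness(s, 0.16, seed = 22)
  d <- derive_daily(s)
  cfg <- threshold_config()
  mmt <- 24.5
  ev <- detect_events(d, meta = list(mmt = mmt, district_id = "I03"), config = cfg)
  q <- qualify_days(d, mmt, cfg)
  # every event day re-checks as qualifying
  for (k in seq_len(nrow(ev))) {
    idx <- which(d$date >= ev$start[k] & d$date <= ev$end[k])
    expect_true(all(q[idx]))
  }
  # sum of durations = qualifying days in runs >= min_duration <= qualifying days
  runs <- oracle_runs(q, cfg$min_duration)
  expect_equal(sum(ev$duration),
               sum(vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))))
  expect_lte(sum(ev$duration), sum(q))
})

test_that("with no MMT mask and min duration 1, event-days equal the hot-day count", {
  s <- generate_series(default_regimes()$I01, seed = 31)
  d <- derive_daily(s)
  ev <- detect_events(d, meta = NULL,
                      config = threshold_config(min_duration = 1))
  expect_equal(sum(ev$duration), count_hot_days(d, 12.8))
})

test_that("raising threshold or MMT never increases event-days; lowering min duration never loses events", {
  s <- generate_series(default_regimes()$I02, seed = 41)
  d <- derive_daily(s)
  days_at <- function(thr, mmt) {
    sum(detect_events(d, meta = list(mmt = mmt, district_id = "X"),
                      config = threshold_config(dtr_threshold = thr))$duration)
  }
  expect_gte(days_at(12.8, 20), days_at(14.8, 20))
  expect_gte(days_at(12.8, 20), days_at(12.8, 24))
  n_at <- function(md) {
    nrow(detect_events(d, config = threshold_config(min_duration = md)))
  }
  expect_gte(n_at(1), n_at(2))
  expect_gte(n_at(2), n_at(4))
})

test_that("the printed longest-event dates span 77 days", {
  expect_identical(event_duration("2015-10-29", "2016-01-13"), 77L)
  expect_identical(event_duration("2016-05-01", "2016-05-01"), 1L)
  expect_error(event_duration("2016-05-02", "2016-05-01"), "after")
})

test_that("event summaries aggregate counts, event-days and maxima with zero-filled groups", {
  expect_equal(nrow(summarise_events(empty <- detect_events(
    derive_daily(toy_series(c(10, 10), tmean = 25))), "season")), 4)
  ze <- summarise_events(empty, "season")
  expect_true(all(ze$n_events == 0) && all(ze$event_days == 0) &&
                all(ze$max_duration == 0))

  ev <- tibble::tibble(
    district_id = "D1",
    start = as.Date(c("2015-01-01", "2015-02-01", "2015-10-29")),
    end = as.Date(c("2015-01-02", "2015-02-03", "2016-01-13")),
    duration = c(2L, 3L, 77L),
    peak_dtr = c(13.5, 14.2, 17.9),
    season = season_of(c("2015-01-01", "2015-02-01", "2015-10-29")),
    year = c(2015L, 2015L, 2015L)
  )
  sm <- summarise_events(ev, "district")
  expect_equal(sm$n_events, 3L)
  expect_equal(sm$event_days, 82L)
  expect_equal(sm$max_duration, 77L)
  expect_equal(sm$max_peak_dtr, 17.9)

  # grouping by year partitions the total event count
  ev2 <- ev
  ev2$year <- c(2015L, 2016L, 2015L)
  by_year <- summarise_events(ev2, "year")
  expect_equal(sum(by_year$n_events), nrow(ev2))

  expect_error(summarise_events(ev, "continent"))
})
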