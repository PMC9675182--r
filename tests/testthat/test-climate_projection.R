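test_that("bilinear interpolation reproduces nodes, cell-centre means and the closed form", {
  grid <- list(lats = c(0, 1), lons = c(0, 1),
               values = matrix(c(0, 2, 1, 3), nrow = 2)) # f(lat,lon) = 2*lat + lon
  expect_equal(bilinear_interpolate(grid, 0, 0), 0)
  expect_equal(bilinear_interpolate(grid, 1, 1), 3)
  expect_equal(bilinear_interpolate(grid, 0.5, 0.5), (0 + 1 + 2 + 3) / 4)
  # hand-evaluated: (1-u)(1-w)a + (1-u)w b + u(1-w)c + u w d at u=.25, w=.75
  expect_equal(bilinear_interpolate(grid, 0.25, 0.75), 1.25)
  expect_error(bilinear_interpolate(grid, 1.5, 0.5), "outside")
})

test_that("bilinear interpolation is linear in field values and matches an independent oracle", {
  withr::with_seed(55, {
    lats <- sort(runif(5, -35, -20))
    lons <- sort(runif(6, 17, 33))
    v1 <- matrix(rnorm(30), 5, 6)
    v2 <- matrix(rnorm(30), 5, 6)
    g1 <- list(lats = lats, lons = lons, values = v1)
    g2 <- list(lats = lats, lons = lons, values = v2)
    g12 <- list(lats = lats, lons = lons, values = 2 * v1 + 3 * v2)
    qlat <- runif(20, min(lats), max(lats))
    qlon <- runif(20, min(lons), max(lons))
    expect_equal(bilinear_interpolate(g12, qlat, qlon),
                 2 * bilinear_interpolate(g1, qlat, qlon) +
                   3 * bilinear_interpolate(g2, qlat, qlon), tolerance = 1e-12)
    skip_if_not_installed("pracma")
    ora <- pracma::interp2(x = lons, y = lats, Z = v1, xp = qlon, yp = qlat,
                           method = "linear")
    expect_equal(bilinear_interpolate(g1, qlat, qlon), ora, tolerance = 1e-12)
  })
})

test_that("zero anomaly is a round-trip identity, values and events alike", {
  regs <- default_regimes()[c("C02", "I01")]
  series <- generate_all_series(regs, seed = 61)
  meta <- synthetic_meta(regs)
  zero <- generate_anomaly("zero", 0, 0, meta)
  fut <- apply_anomaly_all(series, zero, meta, c("2014-01-01", "2019-12-31"))
  for (id in names(series)) {
    expect_equal(fut[[id]]$tmax, series[[id]]$tmax)
    expect_equal(fut[[id]]$tmin, series[[id]]$tmin)
  }
  obs_ev <- detect_events_all(series, meta)
  fut_ev <- detect_events_all(fut, meta)
  expect_equal(as.data.frame(fut_ev), as.data.frame(obs_ev))
})

test_that("a tmax-only delta shifts DTR by exactly that delta; an equal shift leaves DTR alone", {
  regs <- default_regimes()["I02"]
  s <- generate_all_series(regs, seed = 62)$I02
  s <- inject_missingness(s, 0.16, seed = 63)
  meta <- synthetic_meta(regs)
  tmax_only <- generate_anomaly("t", 2, 0, meta)
  fut <- apply_anomaly(s, tmax_only, meta, c("2014-01-01", "2019-12-31"))
  d0 <- derive_daily(s)
  d1 <- derive_daily(fut)
  present <- !is.na(d0$dtr)
  expect_equal(d1$dtr[present], d0$dtr[present] + 2)
  expect_true(all(is.na(d1$dtr[!present]))) # missing days stay missing

  both <- generate_anomaly("b", 1.5, 1.5, meta)
  fut2 <- apply_anomaly(s, both, meta, c("2014-01-01", "2019-12-31"))
  d2 <- derive_daily(fut2)
  expect_equal(d2$dtr[present], d0$dtr[present])
  expect_equal(d2$tmean[present], d0$tmean[present] + 1.5)
})

test_that("the base calendar cycles onto the target period with Feb 29 fallback", {
  regs <- default_regimes()["C01"]
  s <- generate_all_series(regs, seed = 64)$C01
  meta <- synthetic_meta(regs)
  zero <- generate_anomaly("zero", 0, 0, meta)
  fut <- apply_anomaly(s, zero, meta, c("2020-01-01", "2039-12-31"))
  expect_equal(nrow(fut), inclusive_day_count("2020-01-01", "2039-12-31"))
  # 2026 is the 7th target year -> base year cycles back to 2014
  expect_equal(fut$tmax[fut$date == as.Date("2026-03-05")],
               s$tmax[s$date == as.Date("2014-03-05")])
  # 2020 maps from 2014 (non-leap): its Feb 29 falls back to Feb 28
  expect_equal(fut$tmax[fut$date == as.Date("2020-02-29")],
               s$tmax[s$date == as.Date("2014-02-28")])
  # 2022 maps from 2016 (leap): ordinary month/day alignment
  expect_equal(fut$tmin[fut$date == as.Date("2022-02-28")],
               s$tmin[s$date == as.Date("2016-02-28")])
})

test_that("monthly deltas broadcast to all days of the month", {
  regs <- default_regimes()["C01"]
  s <- generate_all_series(regs, seed = 65)$C01
  meta <- synthetic_meta(regs)
  f <- generate_anomaly("m", 1, 0.5, meta, monthly = TRUE)
  jan_boost <- f$delta[f$variable == "tmax" & f$month == 1]
  fut <- apply_anomaly(s, f, meta, c("2014-01-01", "2019-12-31"))
  jan <- format(s$date, "%m") == "01"
  expect_equal(fut$tmax[jan], s$tmax[jan] + jan_boost)
})

test_that("projected days with inverted temperatures are set missing with a warning", {
  s <- daily_series("T1", c("2015-01-01", "2015-12-31"), tmax = c(20, 20),
                    tmin = c(18, 10), period_start = "2015-01-01",
                    period_end = "2015-12-31")
  f <- anomaly_field("x", tibble::tibble(
    variable = c("tmax", "tmin"), district_id = "T1",
    month = NA_integer_, delta = c(0, 5)))
  expect_warning(
    fut <- apply_anomaly(s, f, toy_meta()[1, ], c("2015-01-01", "2015-12-31")),
    "tmax < tmin")
  expect_true(is.na(fut$tmax[1]) && is.na(fut$tmin[1]))
  expect_equal(fut$tmin[nrow(fut)], 15)
})

test_that("projection preconditions are enforced", {
  s <- daily_series("T1", c("2015-03-01", "2015-03-02"), tmax = c(20, 21),
                    tmin = c(10, 11))
  f <- generate_anomaly("x", 1, 1, toy_meta())
  expect_error(apply_anomaly(s, f, toy_meta()[1, ], c("2020-01-01", "2020-12-31")),
               "whole calendar years")
  s2 <- generate_series(default_regimes()$C01, seed = 3)
  f2 <- f[f$district_id != "C01", ]
  expect_error(apply_anomaly(s2, f2, toy_meta()[1, ], c("2020-01-01", "2020-12-31")),
               "no deltas")
})

test_that("percent change matches the printed scenario arithmetic", {
  pc <- pct_change(150, c(270, 281, 150))
  expect_equal(pc$pct_rounded, c(80, 87, 0))
  expect_equal(pc$pct_raw[2], 100 * 131 / 150, tolerance = 1e-12)
  expect_true(is.na(pct_change(0, 10)$pct_raw)) # undefined, not infinite
})

test_that("scenario comparison tables count events and event-days per group", {
  base <- tibble::tibble(
    district_id = "D1",
    start = as.Date(c("2015-01-05", "2015-07-10")),
    end = as.Date(c("2015-01-07", "2015-07-11")),
    duration = c(3L, 2L), peak_dtr = c(14, 13.2),
    season = season_of(c("2015-01-05", "2015-07-10")),
    year = 2015L)
  same <- compare_scenarios(base, list(S = base), by = "season")
  expect_true(all(same$pct_raw[same$observed > 0] == 0))

  extra <- dplyr::bind_rows(base, tibble::tibble(
    district_id = "D1", start = as.Date("2015-12-20"), end = as.Date("2015-12-21"),
    duration = 2L, peak_dtr = 13.1, season = season_of("2015-12-20"), year = 2015L))
  cmp <- compare_scenarios(base, list(S = extra), by = "season")
  ev <- cmp[cmp$measure == "events", ]
  expect_equal(ev$future[ev$group == "summer"], ev$observed[ev$group == "summer"] + 1)
  expect_equal(ev$future[ev$group == "winter"], ev$observed[ev$group == "winter"])
})
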