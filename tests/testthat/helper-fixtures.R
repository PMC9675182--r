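# Shared fixtures and independent oracles, built in code at test time.

# Build a one-district series with prescribed DTR and mean temperature:
# tmin = tmean - dtr/2, tmax = tmean + dtr/2; NA dtr gives a missing day.
toy_series <- function(dtr, tmean = rep(25, length(dtr)), start = "2015-01-01",
                       district_id = "T1") {
  dates <- seq(as.Date(start), by = "day", length.out = length(dtr))
  tmean <- rep_len(tmean, length(dtr))
  tmin <- tmean - dtr / 2
  tmax <- tmean + dtr / 2
  daily_series(district_id, dates, tmax = tmax, tmin = tmin)
}

# Brute-force enumeration of maximal TRUE-runs of length >= min_len,
# by linear scan (independent of the rle-based implementation).
oracle_runs <- function(q, min_len) {
  runs <- list()
  i <- 1L
  n <- length(q)
  while (i <= n) {
    if (q[i]) {
      j <- i
      while (j < n && q[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

# Sort-based percentile with linear interpolation between order statistics.
p95_oracle <- function(x, p = 0.95) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

write_temp_csv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

toy_meta <- function() {
  tibble::tibble(
    district_id = c("T1", "T2"),
    province = c("Prov A", "Prov B"),
    mmt = c(21, 24),
    lat = c(-33.9, -25.6),
    lon = c(18.6, 27.1),
    coastal = c(TRUE, FALSE)
  )
}
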