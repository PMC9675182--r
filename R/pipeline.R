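#' Run the detection stage end to end and write its artifacts
#'
#' Reads (or accepts) daily series and metadata, applies QC, detects
#' heatwave events per district with MMT masking, and writes to `out_dir`:
#' `qc_report.csv`, `events.csv`, `summary_district.csv`,
#' `summary_province.csv`, `summary_season.csv`, `summary_year.csv` and a
#' `manifest.json` recording the configuration (with an MD5 hash) so a rerun
#' from the same inputs is byte-identical.
#'
#' @param input path to a long-format daily CSV, or a named list of
#'   [daily_series()], or the list returned by [read_daily_csv()].
#' @param meta path to a metadata CSV or a metadata tibble.
#' @param config a [threshold_config()].
#' @param out_dir output directory (created if absent).
#' @param apply_mmt logical; disable to detect without MMT masking.
#' @return invisibly, list with `events`, `summaries` (named list of
#'   tibbles), `qc` (or `NULL`), `meta`.
#' @export
run_detection <- function(input, meta, config = threshold_config(),
                          out_dir = ".", apply_mmt = TRUE) {
  if (is.character(meta)) meta <- read_district_meta(meta)
  qc <- NULL
  if (is.character(input)) {
    loaded <- read_daily_csv(input, meta = meta)
    series <- loaded$series
    qc <- loaded$qc
  } else if (is.list(input) && !is.null(input$series)) {
    series <- input$series
    qc <- input$qc
  } else {
    series <- input
  }
  events <- detect_events_all(series, meta = if (apply_mmt) meta else NULL,
                              config = config)
  if (!"province" %in% names(events)) {
    events <- dplyr::left_join(events, meta[, c("district_id", "province")],
                               by = "district_id")
  }
  years <- sort(unique(as.integer(format(
    unlist_dates(lapply(series, function(s) range(s$date)))
  , "%Y"))))
  summaries <- list(
    district = summarise_events(events, "district", levels = meta$district_id),
    province = summarise_events(events, "province", levels = sort(unique(meta$province))),
    season = summarise_events(events, "season"),
    year = summarise_events(events, "year", levels = seq(min(years), max(years)))
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(qc)) write_table(qc, file.path(out_dir, "qc_report.csv"))
  write_table(events, file.path(out_dir, "events.csv"))
  for (nm in names(summaries)) {
    write_table(summaries[[nm]], file.path(out_dir, sprintf("summary_%s.csv", nm)))
  }
  write_manifest(out_dir, stage = "detect", config = config,
                 n_districts = length(series))
  invisible(list(events = events, summaries = summaries, qc = qc, meta = meta))
}

#' Run the projection stage and write per-scenario artifacts
#'
#' Applies each scenario's anomaly field to the observed series
#' (delta-change), re-runs detection over the target period with the same
#' configuration and unchanged MMTs, and writes per scenario
#' `future_events_<scenario>.csv` and `comparison_<scenario>.csv`
#' (observed vs future event counts and event-days with percent change, by
#' season and by district), plus a `manifest.json`.
#'
#' @param series named list of observed [daily_series()].
#' @param meta metadata tibble (or CSV path).
#' @param scenarios named list of [anomaly_field()] (names are labels), or a
#'   path to a long anomaly CSV.
#' @param target_period length-2 projection period.
#' @param config a [threshold_config()].
#' @param out_dir output directory.
#' @param observed_events optional precomputed observed events (else
#'   computed here).
#' @param apply_mmt logical; disable to project without MMT masking.
#' @return invisibly, list with `future_events` (named list),
#'   `comparisons` (named list of tibbles) and `observed_events`.
#' @export
run_projection <- function(series, meta, scenarios,
                           target_period = c("2020-01-01", "2039-12-31"),
                           config = threshold_config(), out_dir = ".",
                           observed_events = NULL, apply_mmt = TRUE) {
  if (is.character(meta)) meta <- read_district_meta(meta)
  if (is.character(scenarios)) scenarios <- read_anomaly_csv(scenarios)
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stop("scenarios must be a named list (names are scenario labels)", call. = FALSE)
  }
  det_meta <- if (apply_mmt) meta else NULL
  if (is.null(observed_events)) {
    observed_events <- detect_events_all(series, meta = det_meta, config = config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  future_events <- list()
  comparisons <- list()
  for (sc in names(scenarios)) {
    fut_series <- apply_anomaly_all(series, scenarios[[sc]], meta, target_period)
    fev <- detect_events_all(fut_series, meta = det_meta, config = config)
    future_events[[sc]] <- fev
    cmp <- dplyr::bind_rows(
      compare_scenarios(observed_events, stats::setNames(list(fev), sc), by = "season"),
      compare_scenarios(observed_events, stats::setNames(list(fev), sc),
                        by = "district", levels = meta$district_id)
    )
    comparisons[[sc]] <- cmp
    write_table(fev, file.path(out_dir, sprintf("future_events_%s.csv", sanitize(sc))))
    write_table(cmp, file.path(out_dir, sprintf("comparison_%s.csv", sanitize(sc))))
  }
  write_manifest(out_dir, stage = "project", config = config,
                 scenarios = names(scenarios), target_period = as.character(target_period))
  invisible(list(future_events = future_events, comparisons = comparisons,
                 observed_events = observed_events))
}

sanitize <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

unlist_dates <- function(x) as.Date(unlist(lapply(x, as.character)))

write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) df[[col]] <- as.character(df[[col]])
    if (is.factor(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

write_manifest <- function(out_dir, stage, config, ...) {
  cfg <- unclass(config)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), tmp)
  manifest <- c(list(stage = stage, config = cfg,
                     config_md5 = unname(tools::md5sum(tmp))),
                list(...))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
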