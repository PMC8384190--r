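#' Sensor file dialect
#'
#' Describes the delimited-text layout of logger exports: delimiter, column
#' names, timestamp format and timezone, missing-value token and the
#' declared logging grid.
#'
#' @param delim Field delimiter.
#' @param col_timestamp,col_do,col_temp,col_depth Column names.
#' @param ts_format Timestamp format string.
#' @param tz Timezone of the sensor clock (use a fixed-offset zone for
#'   local standard time).
#' @param na Missing-value token.
#' @param dt_min Declared logging interval, minutes.
#' @return List of class `sensor_dialect`.
#' @export
sensor_dialect <- function(delim = ",", col_timestamp = "timestamp",
                           col_do = "do_mgl", col_temp = "temp_c",
                           col_depth = "depth_m",
                           ts_format = "%Y-%m-%d %H:%M:%S",
                           tz = "Etc/GMT+5", na = "NA", dt_min = 15) {
  structure(list(delim = delim, col_timestamp = col_timestamp,
                 col_do = col_do, col_temp = col_temp,
                 col_depth = col_depth, ts_format = ts_format, tz = tz,
                 na = na, dt_min = dt_min), class = "sensor_dialect")
}

#' Write a sensor series as delimited text
#'
#' @param series A [do_series()].
#' @param path Output file.
#' @param dialect A [sensor_dialect()].
#' @param qc Include the QC flag column.
#' @return `path`, invisibly.
#' @export
write_sensor_file <- function(series, path, dialect = sensor_dialect(),
                              qc = TRUE) {
  df <- data.frame(format(series$timestamp, dialect$ts_format), series$do,
                   series$temp, series$depth, stringsAsFactors = FALSE)
  names(df) <- c(dialect$col_timestamp, dialect$col_do, dialect$col_temp,
                 dialect$col_depth)
  if (qc) df$qc <- series$qc
  utils::write.table(df, path, sep = dialect$delim, row.names = FALSE,
                     quote = FALSE, na = dialect$na)
  invisible(path)
}

#' Read a sensor file onto its declared regular grid
#'
#' Parses the file per the dialect, validates timestamps (unparseable rows
#' error with their line number; duplicates error), and regularises onto
#' the declared grid from the first to the last sample: grid slots with no
#' row become `missing` samples, and a warning reports when more than half
#' the grid is unfilled (e.g. a 30-minute series declared as 15-minute).
#'
#' @param path Input file.
#' @param dialect A [sensor_dialect()].
#' @param site_id,latitude,longitude Site metadata for the series.
#' @return A [do_series()].
#' @export
read_sensor_file <- function(path, dialect = sensor_dialect(),
                             site_id = "site", latitude = NA_real_,
                             longitude = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delim,
                           na.strings = dialect$na, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c(dialect$col_timestamp, dialect$col_do, dialect$col_temp)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(raw[[dialect$col_timestamp]], format = dialect$ts_format,
                   tz = dialect$tz)
  bad <- which(is.na(ts) & !is.na(raw[[dialect$col_timestamp]]))
  if (length(bad))
    stop("unparseable timestamp at line ", bad[1] + 1, ": ",
         raw[[dialect$col_timestamp]][bad[1]])
  if (anyDuplicated(ts)) stop("duplicate timestamps in ", path)
  o <- order(ts)
  raw <- raw[o, ]; ts <- ts[o]
  grid <- seq(ts[1], ts[length(ts)], by = dialect$dt_min * 60)
  idx <- match(as.numeric(grid), as.numeric(ts))
  off_grid <- setdiff(seq_along(ts), idx[!is.na(idx)])
  if (length(off_grid)) {
    message(length(off_grid),
            " row(s) off the declared grid were dropped (first at line ",
            off_grid[1] + 1, ")")
  }
  do <- raw[[dialect$col_do]][idx]
  temp <- raw[[dialect$col_temp]][idx]
  depth <- if (dialect$col_depth %in% names(raw))
    raw[[dialect$col_depth]][idx] else NA_real_
  qc <- if ("qc" %in% names(raw)) raw$qc[idx] else rep("ok", length(grid))
  qc[is.na(qc) | is.na(idx) | is.na(do)] <- "missing"
  frac_missing <- mean(is.na(idx))
  if (frac_missing >= 1 / 3)
    warning(sprintf("%.0f%% of the declared %d-min grid is unfilled; %s",
                    100 * frac_missing, dialect$dt_min,
                    "check the dialect's logging interval"))
  do_series(grid, do = do, temp = temp, depth = depth, qc = qc,
            site_id = site_id, latitude = latitude, longitude = longitude,
            dt_min = dialect$dt_min)
}

#' Run the full analysis pipeline on a network scenario
#'
#' Executes the stages end to end on simulated data with known truth:
#' simulate each site of the scenario, inject artifacts if specified, run
#' QAQC, classify seasons from the first upstream site's temperature,
#' two-pass metabolism fitting per site, upstream-downstream amplification
#' per pair and season, the pairwise Kruskal-Wallis matrix, and the
#' moving-window violation analysis. All stage tables are written as
#' delimited text in `out_dir` together with a machine-readable run
#' manifest (seed, package version, config hash). Any stage failure writes
#' a FAILED marker naming the stage and rethrows.
#'
#' @param scenario A [make_network_scenario()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest, enforcing the write-once contract).
#' @param config A [sim_config()] template.
#' @param artifacts Optional [artifact_spec()] applied to every site.
#' @param qaqc A [qaqc_config()].
#' @param priors,control Metabolism settings (see [metab_priors()],
#'   [mcmc_control()]).
#' @param criteria A [criteria_config()].
#' @param leaf_out_date Leaf-out date for the season classifier; NULL
#'   derives a single-season calendar.
#' @return Invisible list with the stage outputs (`series`, `qaqc_reports`,
#'   `metabolism`, `amplification`, `pairwise`, `violations`, `seasons`,
#'   `manifest`).
#' @export
run_pipeline <- function(scenario, out_dir, config = NULL,
                         artifacts = NULL, qaqc = qaqc_config(),
                         priors = metab_priors(), control = mcmc_control(),
                         criteria = criteria_config(),
                         leaf_out_date = NULL) {
  stopifnot(inherits(scenario, "network_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.exists(file.path(out_dir, "manifest.yaml")))
    stop("out_dir already holds a run; refusing to overwrite")
  stage <- "simulate"
  result <- tryCatch({
    sims <- simulate_scenario(scenario, config)
    if (is.null(config)) config <- sim_config(scenario$start, scenario$end)
    series <- lapply(sims, `[[`, "series")
    if (!is.null(artifacts)) {
      series <- lapply(series, function(s) {
        inject_artifacts(s, artifacts, seed = config$seed)$series
      })
    }
    stage <<- "qaqc"
    if (!is.null(scenario$storms)) qaqc$storms <- scenario$storms
    cleaned <- lapply(series, run_qaqc, config = qaqc)
    reports <- lapply(cleaned, `[[`, "report")
    cleaned <- lapply(cleaned, `[[`, "series")
    stage <<- "seasons"
    ref <- cleaned[[1]]
    seasons <- if (!is.null(leaf_out_date)) {
      classify_seasons(series_dates(ref), ref$temp, leaf_out_date)
    } else {
      data.frame(start = min(series_dates(ref)), end = max(series_dates(ref)),
                 label = "all", provenance = "record")
    }
    stage <<- "metabolism"
    fits <- lapply(cleaned, fit_site, priors = priors, control = control)
    usable <- lapply(fits, function(f) filter_estimates(f)$usable)
    stage <<- "comparison"
    amp <- list()
    for (j in unique(scenario$sites$pair)) {
      ids <- scenario$sites$id[scenario$sites$pair == j]
      up_id <- ids[scenario$sites$role[scenario$sites$pair == j] == "upstream"]
      dn_id <- setdiff(ids, up_id)
      pr <- paired_days(usable[[up_id]], usable[[dn_id]])
      for (rate in c("gpp", "er")) {
        a <- amplification(pr, rate, calendar = seasons)
        a$pair <- j; a$rate <- rate
        amp[[length(amp) + 1]] <- a
      }
    }
    amp <- do.call(rbind, amp)
    pw <- if (length(usable) >= 2)
      pairwise_site_matrix(lapply(usable, `[[`, "gpp")) else NULL
    stage <<- "windows"
    metrics <- lapply(cleaned, daily_metrics, coverage = criteria$coverage)
    viol <- count_violations(metrics, criteria = criteria)
    stage <<- "write"
    for (id in names(fits)) {
      utils::write.csv(fits[[id]],
                       file.path(out_dir, paste0("metabolism_", id, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(amp, file.path(out_dir, "amplification.csv"),
                     row.names = FALSE)
    utils::write.csv(viol, file.path(out_dir, "violations.csv"),
                     row.names = FALSE)
    utils::write.csv(seasons, file.path(out_dir, "season_calendar.csv"),
                     row.names = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(list(seed = config$seed, scenario_sites = scenario$sites$id,
                          factors = as.list(scenario$factors),
                          dt_min = config$dt_min, depth = config$depth),
                     cfg_path)
    manifest <- list(package = "dielmetab",
                     version = as.character(utils::packageVersion("dielmetab")),
                     r_version = R.version.string,
                     seed = config$seed,
                     config_hash = unname(tools::md5sum(cfg_path)))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    list(series = cleaned, qaqc_reports = reports, metabolism = fits,
         amplification = amp, pairwise = pw, violations = viol,
         seasons = seasons, manifest = manifest)
  }, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
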