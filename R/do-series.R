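#' Quality-control flag levels for sensor samples
#'
#' Flags partition samples: exactly one flag per sample. `despiked` and
#' `smoothed` samples carry corrected values and remain usable; all
#' `removed_*` and `missing` samples are excluded from analysis.
#' @export
qc_levels <- c("ok", "removed_clog", "removed_storm_day", "despiked",
               "smoothed", "removed_no_diel", "removed_drift", "missing")

#' Construct a dissolved-oxygen sensor time series
#'
#' The central container of the pipeline: a data.frame on a strict regular
#' time grid with per-sample DO, temperature, optional depth, and a QC flag,
#' plus site metadata carried as attributes.
#'
#' @param timestamp POSIXct, strictly increasing on a fixed grid.
#' @param do Dissolved oxygen, mg L^-1 (NA allowed where flagged missing).
#' @param temp Water temperature, degrees C.
#' @param depth Water depth, m (optional, NA allowed).
#' @param qc Per-sample flag from [qc_levels] (default "ok").
#' @param site_id Site identifier, e.g. "D-B-14.5".
#' @param latitude,longitude Site coordinates, decimal degrees.
#' @param dt_min Grid spacing in minutes; inferred from timestamps if NULL.
#' @return data.frame of class `do_series`.
#' @export
do_series <- function(timestamp, do, temp, depth = NA_real_, qc = "ok",
                      site_id = "site", latitude = NA_real_,
                      longitude = NA_real_, dt_min = NULL) {
  if (!inherits(timestamp, "POSIXct")) stop("timestamp must be POSIXct")
  n <- length(timestamp)
  steps <- as.numeric(diff(timestamp), units = "mins")
  if (n > 1) {
    if (any(steps <= 0)) stop("timestamps must be strictly increasing")
    if (is.null(dt_min)) dt_min <- min(steps)
    if (any(abs(steps - dt_min) > 1e-6))
      stop("timestamps must lie on a regular ", dt_min, "-minute grid")
    if ((24 * 60) %% dt_min != 0)
      stop("timestep must divide 24 h evenly")
  } else if (is.null(dt_min)) dt_min <- 15
  qc <- rep_len(as.character(qc), n)
  if (!all(qc %in% qc_levels)) stop("unknown qc flag")
  do <- rep_len(as.numeric(do), n)
  if (any(do[qc == "ok"] < 0, na.rm = TRUE))
    stop("negative DO on samples flagged ok")
  x <- data.frame(timestamp = timestamp, do = do,
                  temp = rep_len(as.numeric(temp), n),
                  depth = rep_len(as.numeric(depth), n), qc = qc,
                  stringsAsFactors = FALSE)
  structure(x, class = c("do_series", "data.frame"), site_id = site_id,
            latitude = latitude, longitude = longitude, dt_min = dt_min)
}

# reconstruct a do_series from a modified data.frame, keeping metadata
rebuild_series <- function(df, template) {
  structure(as.data.frame(df), class = c("do_series", "data.frame"),
            site_id = attr(template, "site_id"),
            latitude = attr(template, "latitude"),
            longitude = attr(template, "longitude"),
            dt_min = attr(template, "dt_min"))
}

#' @export
print.do_series <- function(x, ...) {
  cat(sprintf("<do_series> site %s: %d samples at %g min, %s to %s\n",
              attr(x, "site_id"), nrow(x), attr(x, "dt_min"),
              format(min(x$timestamp)), format(max(x$timestamp))))
  cat("qc flags:\n")
  print(table(x$qc))
  invisible(x)
}

# calendar day (Date, in the series' own timezone) of each sample
series_dates <- function(series) {
  as.Date(format(series$timestamp, "%Y-%m-%d"))
}

# samples expected per full day
samples_per_day <- function(series) {
  as.integer(24 * 60 / attr(series, "dt_min"))
}
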