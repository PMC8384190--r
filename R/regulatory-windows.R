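#' Regulatory DO criteria configuration
#'
#' Chronic criteria evaluated on moving monitoring windows: the state
#' criterion flags a window whose mean of daily means falls below 6
#' mg L^-1, the federal criterion one whose mean of daily minima falls
#' below 5 mg L^-1; both use strict inequality. Some regulations also count
#' any single day with a minimum below 5 mg L^-1.
#'
#' @param padep_mean Threshold on the window mean of daily means, mg L^-1.
#' @param epa_min Threshold on the window mean of daily minima, mg L^-1.
#' @param single_day Threshold for single-day violations, mg L^-1.
#' @param max_gap Maximum calendar gap (days) between consecutive
#'   measurement days inside a window.
#' @param coverage Minimum fraction of expected samples for a valid daily
#'   metric.
#' @return List of class `criteria_config`.
#' @export
criteria_config <- function(padep_mean = 6, epa_min = 5, single_day = 5,
                            max_gap = 3, coverage = 0.8) {
  if (any(c(padep_mean, epa_min, single_day, max_gap, coverage) <= 0))
    stop("all criteria thresholds must be > 0")
  structure(list(padep_mean = padep_mean, epa_min = epa_min,
                 single_day = single_day, max_gap = max_gap,
                 coverage = coverage), class = "criteria_config")
}

#' Daily DO metrics from a cleaned sensor series
#'
#' Per-day mean, minimum, maximum and amplitude over usable samples; days
#' under the coverage threshold are omitted and listed in the "omitted"
#' attribute.
#'
#' @param series A cleaned [do_series()].
#' @param coverage Minimum fraction of expected samples.
#' @return data.frame with columns `date`, `mean`, `min`, `max`,
#'   `amplitude`, `coverage`.
#' @export
daily_metrics <- function(series, coverage = 0.8) {
  day <- series_dates(series)
  expected <- samples_per_day(series)
  usable <- series$qc %in% usable_flags & !is.na(series$do)
  rows <- lapply(unique(day), function(d) {
    x <- series$do[usable & day == d]
    cov <- length(x) / expected
    data.frame(date = d, mean = if (length(x)) mean(x) else NA_real_,
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               amplitude = if (length(x)) max(x) - min(x) else NA_real_,
               coverage = cov)
  })
  out <- do.call(rbind, rows)
  keep <- out$coverage >= coverage
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "omitted") <- out$date[!keep]
  res
}

#' Enumerate monitoring windows of N measurement days
#'
#' A window is any run of N consecutive measurement days (one window per
#' eligible start day) in which every adjacent pair of member days differs
#' by at most `max_gap` calendar days -- so a 3-day window may span up to 7
#' calendar days when gaps are allowed.
#'
#' @param days Sorted unique measurement days (Date).
#' @param n Nominal window length in measurement days.
#' @param max_gap Maximum calendar gap between adjacent member days.
#' @return List of Date vectors, each of length `n`; empty list when no
#'   window is eligible.
#' @export
enumerate_windows <- function(days, n, max_gap = 3) {
  days <- sort(unique(as.Date(days)))
  m <- length(days)
  if (m < n) return(list())
  gaps <- as.numeric(diff(days))
  out <- list()
  for (s in seq_len(m - n + 1)) {
    if (n == 1 || all(gaps[s:(s + n - 2)] <= max_gap))
      out[[length(out) + 1]] <- days[s:(s + n - 1)]
  }
  out
}

#' Complete a window skeleton with its DO statistics and verdicts
#'
#' @param window Date vector of member days (from [enumerate_windows()]).
#' @param metrics Daily metrics table ([daily_metrics()]); all member days
#'   must be present, else NULL is returned.
#' @param criteria A [criteria_config()].
#' @return One-row data.frame: `start`, `end`, `n`, `window_mean`
#'   (mean of member daily means), `window_mean_min` (mean of member daily
#'   minima), `padep_mean` and `epa_min` violation flags (strict <).
#' @export
window_stats <- function(window, metrics, criteria = criteria_config()) {
  idx <- match(as.character(window), as.character(metrics$date))
  if (anyNA(idx)) return(NULL)
  wm <- mean(metrics$mean[idx])
  wmm <- mean(metrics$min[idx])
  data.frame(start = window[1], end = window[length(window)],
             n = length(window), window_mean = wm, window_mean_min = wmm,
             padep_mean = wm < criteria$padep_mean,
             epa_min = wmm < criteria$epa_min)
}

#' Count criterion violations across window lengths
#'
#' Enumerates every eligible window of each length from a site's daily
#' metrics and tallies windows violating each chronic criterion.
#'
#' @param metrics Daily metrics table (or a named list of them, one per
#'   site).
#' @param lengths Window lengths in measurement days.
#' @param criteria A [criteria_config()].
#' @return data.frame with one row per site x length: `n_windows`,
#'   `padep_mean`, `epa_min` counts and the corresponding fractions.
#' @export
count_violations <- function(metrics, lengths = c(3, 7, 15, 30),
                             criteria = criteria_config()) {
  if (is.data.frame(metrics)) metrics <- list(site = metrics)
  rows <- list()
  for (site in names(metrics)) {
    mt <- metrics[[site]]
    for (n in lengths) {
      wins <- enumerate_windows(mt$date, n, criteria$max_gap)
      stats_ <- lapply(wins, window_stats, metrics = mt, criteria = criteria)
      stats_ <- do.call(rbind, stats_[!vapply(stats_, is.null, logical(1))])
      nw <- if (is.null(stats_)) 0L else nrow(stats_)
      np <- if (nw) sum(stats_$padep_mean) else 0L
      ne <- if (nw) sum(stats_$epa_min) else 0L
      rows[[length(rows) + 1]] <- data.frame(
        site = site, length = n, n_windows = nw,
        padep_mean = np, epa_min = ne,
        frac_padep = if (nw) np / nw else NA_real_,
        frac_epa = if (nw) ne / nw else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-day violations and their capture by monitoring windows
#'
#' Counts days whose daily minimum falls below the threshold, and for each
#' window length summarises the empirical distribution of how many such
#' days a single monitoring window would capture.
#'
#' @param metrics Daily metrics table.
#' @param threshold Daily-minimum threshold, mg L^-1.
#' @param lengths Window lengths.
#' @param criteria A [criteria_config()] (supplies `max_gap`).
#' @return List with `n_violation_days` and `capture` (data.frame per
#'   length: min, q25, median, q75, max of captured counts, plus
#'   `n_windows`).
#' @export
single_day_violations <- function(metrics, threshold = 5,
                                  lengths = c(3, 7, 15, 30),
                                  criteria = criteria_config()) {
  viol <- metrics$date[metrics$min < threshold]
  rows <- list()
  for (n in lengths) {
    wins <- enumerate_windows(metrics$date, n, criteria$max_gap)
    caps <- vapply(wins, function(w) sum(w %in% viol), integer(1))
    if (!length(caps)) caps <- 0L
    qs <- stats::quantile(caps, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      length = n, n_windows = length(wins), min = qs[1], q25 = qs[2],
      median = qs[3], q75 = qs[4], max = qs[5])
  }
  list(n_violation_days = length(viol), capture = do.call(rbind, rows))
}
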