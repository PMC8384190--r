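#' Modeled clear-sky photosynthetically active radiation
#'
#' Computes solar zenith angle from the NOAA solar-position equations
#' (Spencer fractional-year series for declination and the equation of time,
#' hour angle from true solar time) and returns a clear-sky PAR ceiling
#' scaled by the cosine of the zenith angle. Only relative light within a
#' day matters for metabolism fitting (the model uses normalised light
#' fractions), so the absolute ceiling is cosmetic.
#'
#' @param timestamps POSIXct vector with a resolved timezone. Timestamps are
#'   interpreted with their own UTC offset, so fixed-offset zones such as
#'   "Etc/GMT+5" give local standard time year-round.
#' @param latitude,longitude Site coordinates, decimal degrees (east/north
#'   positive).
#' @param par_max Clear-sky PAR at zenith 0, umol m^-2 s^-1 (default 2300).
#' @return data.frame with columns `timestamp` and `par` (>= 0, zero when
#'   the sun is below the horizon).
#' @export
modeled_par <- function(timestamps, latitude, longitude, par_max = 2300) {
  if (abs(latitude) > 90) stop("latitude must lie in [-90, 90]")
  if (abs(longitude) > 180) stop("longitude must lie in [-180, 180]")
  if (!inherits(timestamps, "POSIXct")) stop("timestamps must be POSIXct")
  cz <- cos_zenith(timestamps, latitude, longitude)
  data.frame(timestamp = timestamps, par = par_max * pmax(cz, 0))
}

# cosine of solar zenith via NOAA general solar position equations
cos_zenith <- function(timestamps, latitude, longitude) {
  doy <- as.integer(format(timestamps, "%j"))
  hour <- as.integer(format(timestamps, "%H")) +
    as.integer(format(timestamps, "%M")) / 60 +
    as.numeric(format(timestamps, "%S")) / 3600
  # UTC offset in hours from the timestamp's own zone (e.g. "-0500" -> -5)
  zoff <- as.integer(format(timestamps, "%z"))
  tz_hours <- sign(zoff) * (abs(zoff) %/% 100 + (abs(zoff) %% 100) / 60)
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24) # fractional year, rad
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g)) # minutes
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g) # radians
  time_offset <- eqtime + 4 * longitude - 60 * tz_hours
  tst <- hour * 60 + time_offset # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180 # hour angle, radians
  lat <- latitude * pi / 180
  sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
}

#' Per-timestep light fractions for distributing daily GPP
#'
#' Normalises a vector of PAR values so they sum to one; the one-station
#' model allocates the daily GPP total across timesteps with these weights.
#'
#' @param par Non-negative PAR values for the timesteps of one day.
#' @return Weights summing to 1.
#' @export
light_fractions <- function(par) {
  if (any(par < 0)) stop("par must be >= 0")
  s <- sum(par)
  if (s <= 0) stop("no positive light in the day; cannot form light fractions")
  par / s
}

#' Potential incident light (PIL) of a monitored reach
#'
#' PIL is the ratio of visible (unshaded) channel area under leaf-out canopy
#' to the area under leaf-off conditions, a canopy-openness proxy measured
#' per 100-m longitudinal section of the reach upstream of a sensor. The
#' site value is the mean of its section ratios; reach-average width is the
#' total leaf-off area divided by the reach length.
#'
#' @param sections data.frame with columns `leaf_off_area_m2` and
#'   `leaf_on_area_m2`, one row per longitudinal section.
#' @param section_length_m Length of each section in metres (default 100).
#' @return List with `pil_pct` (mean section ratio, percent), `pil_se_pct`
#'   (standard error across sections, NA for a single section), and
#'   `width_m`.
#' @export
compute_pil <- function(sections, section_length_m = 100) {
  stopifnot(is.data.frame(sections), nrow(sections) >= 1)
  off <- sections$leaf_off_area_m2
  on <- sections$leaf_on_area_m2
  if (any(off <= 0)) stop("leaf-off area must be > 0")
  if (any(on < 0)) stop("leaf-on area must be >= 0")
  ratio <- on / off
  se <- if (length(ratio) > 1) stats::sd(ratio) / sqrt(length(ratio)) else NA_real_
  list(
    pil_pct = 100 * mean(ratio),
    pil_se_pct = 100 * se,
    width_m = sum(off) / (section_length_m * nrow(sections))
  )
}

#' Classify seasons from weekly temperature and a leaf-out date
#'
#' Implements a three-season calendar for a temperate deciduous watershed:
#' spring ends at the regional leaf-out date; summer/fall ends when average
#' weekly water temperature (at a reference site upstream of effluent
#' influence) first *remains* below `threshold` until the winter exit; and
#' winter ends when weekly temperature first remains at or above the
#' threshold through the end of the record. "Remains" requires persistence:
#' an isolated cold week does not start winter.
#'
#' @param dates Date vector of daily observations (sorted, no gaps needed).
#' @param temps Daily mean water temperature, degrees C, same length.
#' @param leaf_out_date Date of regional average leaf-out.
#' @param threshold Temperature threshold, degrees C (default 4).
#' @param week_start Weekday anchoring weekly means (1 = Monday).
#' @return data.frame with columns `start`, `end`, `label` in
#'   {"spring", "summer/fall", "winter"} and `provenance`; intervals are
#'   contiguous (`end` of one is the day before `start` of the next) and
#'   cover the record.
#' @export
classify_seasons <- function(dates, temps, leaf_out_date, threshold = 4,
                             week_start = 1) {
  stopifnot(length(dates) == length(temps))
  dates <- as.Date(dates)
  leaf_out_date <- as.Date(leaf_out_date)
  if (leaf_out_date < min(dates) || leaf_out_date > max(dates))
    stop("leaf_out_date must fall inside the record")
  # calendar-aligned weeks (Monday by default)
  wstart <- dates - ((as.integer(format(dates, "%u")) - week_start) %% 7)
  wk <- stats::aggregate(temps, by = list(week = wstart), FUN = mean)
  names(wk) <- c("week", "temp")
  wk <- wk[order(wk$week), ]
  cold <- wk$temp < threshold
  n <- nrow(wk)
  bounds <- list()
  if (!any(cold)) {
    warning("no week below threshold: record has no winter")
    winter_start <- winter_end <- NULL
  } else {
    last_cold <- max(which(cold))
    # winter exit: first week after the cold run whose successors stay warm
    winter_end <- if (last_cold < n) wk$week[last_cold + 1] else NULL
    # winter entry: start of the trailing run of consecutive cold weeks
    last_warm_before <- if (any(!cold[seq_len(last_cold)])) {
      max(which(!cold[seq_len(last_cold)]))
    } else 0
    winter_start <- wk$week[last_warm_before + 1]
    if (winter_start <= leaf_out_date)
      stop("winter onset precedes leaf-out; record too short to classify")
  }
  rec_start <- min(dates)
  rec_end <- max(dates)
  seg <- function(s, e, lab, prov) {
    data.frame(start = s, end = e, label = lab, provenance = prov,
               stringsAsFactors = FALSE)
  }
  out <- seg(rec_start, leaf_out_date - 1, "spring", "leaf-out date")
  if (is.null(winter_start)) {
    out <- rbind(out, seg(leaf_out_date, rec_end, "summer/fall", "series end"))
  } else {
    out <- rbind(out, seg(leaf_out_date, winter_start - 1, "summer/fall",
                          "temperature rule"))
    if (is.null(winter_end)) {
      out <- rbind(out, seg(winter_start, rec_end, "winter", "series end"))
    } else {
      out <- rbind(out, seg(winter_start, winter_end - 1, "winter",
                            "temperature rule"))
      out <- rbind(out, seg(winter_end, rec_end, "spring", "series end"))
    }
  }
  out <- out[out$end >= out$start, ]
  rownames(out) <- NULL
  out
}

#' Look up the season label of each date in a season calendar
#'
#' @param dates Date vector.
#' @param calendar A season calendar from [classify_seasons()].
#' @return Character vector of labels (NA outside the calendar).
#' @export
season_of <- function(dates, calendar) {
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(calendar))) {
    sel <- dates >= calendar$start[i] & dates <= calendar$end[i]
    out[sel] <- calendar$label[i]
  }
  out
}
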