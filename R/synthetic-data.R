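#' Configuration for the synthetic diel-oxygen generator
#'
#' Defaults emulate the study system the pipeline targets: a shallow
#' (0.2--0.5 m) temperate suburban stream logged at 15-minute intervals,
#' with sensor accuracy of 0.1--0.5 mg L^-1 motivating the observation-noise
#' default. Temperature is a minimal sinusoidal driver (diel + seasonal
#' component) sufficient to exercise the saturation physics.
#'
#' @param start,end First and last simulated calendar day (Date or string).
#' @param latitude,longitude Site coordinates, decimal degrees.
#' @param tz Fixed-offset timezone of the sensor clock (local standard time).
#' @param dt_min Logging interval, minutes; must divide 24 h evenly.
#' @param depth Mean reach depth z, m (> 0).
#' @param temp_mean,temp_diel_amp,temp_seasonal_amp Sinusoidal water
#'   temperature model: annual mean, full diel amplitude and seasonal
#'   amplitude, degrees C. Seasonal peak is late July; diel peak 16:00.
#' @param sigma_obs Observation noise sd, mg L^-1 per sample.
#' @param sigma_proc Process noise sd, mg L^-1 per step.
#' @param do_init Initial DO, mg L^-1, or "saturation".
#' @param par_max Clear-sky PAR ceiling passed to [modeled_par()].
#' @param seed RNG seed used by [simulate_do_series()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(start, end, latitude = 40.19, longitude = -75.28,
                       tz = "Etc/GMT+5", dt_min = 15, depth = 0.3,
                       temp_mean = 15, temp_diel_amp = 2,
                       temp_seasonal_amp = 8, sigma_obs = 0.2,
                       sigma_proc = 0.05, do_init = "saturation",
                       par_max = 2300, seed = 1) {
  if ((24 * 60) %% dt_min != 0) stop("dt_min must divide 24 h evenly")
  if (depth <= 0) stop("depth must be > 0")
  if (sigma_obs < 0 || sigma_proc < 0) stop("noise sds must be >= 0")
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end precedes start")
  structure(list(start = start, end = end, latitude = latitude,
                 longitude = longitude, tz = tz, dt_min = dt_min,
                 depth = depth, temp_mean = temp_mean,
                 temp_diel_amp = temp_diel_amp,
                 temp_seasonal_amp = temp_seasonal_amp,
                 sigma_obs = sigma_obs, sigma_proc = sigma_proc,
                 do_init = do_init, par_max = par_max, seed = seed),
            class = "sim_config")
}

#' Daily true metabolism parameters
#'
#' @param dates Calendar days (Date).
#' @param gpp Daily gross primary production, g O2 m^-2 d^-1 (>= 0).
#' @param er Daily ecosystem respiration, g O2 m^-2 d^-1 (<= 0 by
#'   convention).
#' @param k600 Gas-exchange rate normalised to Sc 600, d^-1 (> 0 allowed 0
#'   for closed-system tests).
#' @return data.frame with one row per day.
#' @export
true_day_params <- function(dates, gpp, er, k600) {
  dates <- as.Date(dates)
  n <- length(dates)
  gpp <- rep_len(gpp, n); er <- rep_len(er, n); k600 <- rep_len(k600, n)
  if (any(gpp < 0)) stop("gpp must be >= 0")
  if (any(er > 0)) stop("er must be <= 0")
  if (any(k600 < 0)) stop("k600 must be >= 0")
  if (anyDuplicated(dates)) stop("duplicate dates")
  data.frame(date = dates, gpp = gpp, er = er, k600 = k600)
}

#' Draw daily parameters spanning realistic ranges
#'
#' Defaults span the annual medians observed across the study network
#' (GPP 2--8, ER -11 to -3 g O2 m^-2 d^-1, K600 4--12 d^-1). Marginals are
#' uniform over the ranges; by default consecutive days are persistent
#' (AR(1) Gaussian copula), reflecting the strong day-to-day autocorrelation
#' of ecosystem metabolism driven by light, temperature and standing
#' biomass. Set `rho = 0` for independent days.
#'
#' @param dates Calendar days.
#' @param gpp_range,er_range,k600_range Sampling ranges.
#' @param rho Day-to-day copula autocorrelation in \[0, 1).
#' @return A [true_day_params()] table.
#' @export
draw_day_params <- function(dates, gpp_range = c(2, 8),
                            er_range = c(-11, -3), k600_range = c(4, 12),
                            rho = 0.85) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  n <- length(dates)
  ar_unif <- function() {
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    for (t in seq_len(n - 1))
      z[t + 1] <- rho * z[t] + stats::rnorm(1, 0, sqrt(1 - rho^2))
    stats::pnorm(z)
  }
  scale_to <- function(u, r) r[1] + u * (r[2] - r[1])
  true_day_params(dates,
                  gpp = scale_to(ar_unif(), gpp_range),
                  er = scale_to(ar_unif(), sort(er_range)),
                  k600 = scale_to(ar_unif(), k600_range))
}

# sinusoidal water temperature driver (seasonal peak ~Jul 24, diel peak 16:00)
sim_temperature <- function(timestamps, config) {
  doy <- as.integer(format(timestamps, "%j"))
  hour <- as.integer(format(timestamps, "%H")) +
    as.integer(format(timestamps, "%M")) / 60
  config$temp_mean +
    config$temp_seasonal_amp * cos(2 * pi * (doy - 205) / 365) +
    config$temp_diel_amp / 2 * sin(2 * pi * (hour - 10) / 24)
}

#' Simulate a diel dissolved-oxygen series with known daily metabolism
#'
#' Forward-integrates the one-station oxygen mass balance (the same
#' semi-implicit recursion the fitting model uses, see [forward_do()]) under
#' modeled clear-sky light, adding Gaussian process noise to the state at
#' each step and independent Gaussian observation noise to each sample.
#'
#' @param params A [true_day_params()] table covering every day in the
#'   configured range.
#' @param config A [sim_config()].
#' @return List with `series` (a [do_series()] with all samples flagged ok)
#'   and `truth` (list with `params` and `states`, the latent pre-observation
#'   DO states plus the temperature and light drivers).
#' @export
simulate_do_series <- function(params, config) {
  stopifnot(inherits(config, "sim_config"))
  days <- seq(config$start, config$end, by = "day")
  miss <- setdiff(as.character(days), as.character(params$date))
  if (length(miss))
    stop("missing day parameters for: ", paste(miss, collapse = ", "))
  set.seed(config$seed)
  dt_min <- config$dt_min
  ts <- seq(as.POSIXct(paste(config$start, "00:00:00"), tz = config$tz),
            as.POSIXct(paste(config$end, "23:59:59"), tz = config$tz),
            by = dt_min * 60)
  n <- length(ts)
  temp <- sim_temperature(ts, config)
  par <- modeled_par(ts, config$latitude, config$longitude,
                     par_max = config$par_max)$par
  day <- as.Date(format(ts, "%Y-%m-%d"))
  # per-day light weights; samples at night carry zero weight so the
  # per-transition weights of each day still sum to (effectively) one
  w <- stats::ave(par, day, FUN = function(p) {
    s <- sum(p); if (s > 0) p / s else rep(0, length(p))
  })
  di <- match(day, params$date)
  dt_days <- dt_min / (24 * 60)
  z <- config$depth
  osat <- o2_saturation(temp)
  kvec <- k600_to_ko2(params$k600[di], temp)
  # transition i: sample i -> i + 1, using day/weight/k of sample i
  i <- seq_len(n - 1)
  kdt2 <- kvec[i] * dt_days / 2
  cinv <- 1 / (1 + kdt2)
  a <- (1 - kdt2) * cinv
  b <- (params$gpp[di[i]] / z * w[i] + params$er[di[i]] / z * dt_days +
        kvec[i] * dt_days * (osat[i] + osat[i + 1]) / 2) * cinv
  eps <- stats::rnorm(n - 1, 0, config$sigma_proc)
  x <- numeric(n)
  x[1] <- if (identical(config$do_init, "saturation")) osat[1] else
    as.numeric(config$do_init)
  for (j in i) x[j + 1] <- a[j] * x[j] + b[j] + eps[j] * cinv[j]
  do_obs <- x + stats::rnorm(n, 0, config$sigma_obs)
  series <- do_series(ts, do = pmax(do_obs, 0), temp = temp, depth = z,
                      qc = "ok", site_id = "sim",
                      latitude = config$latitude,
                      longitude = config$longitude, dt_min = dt_min)
  truth <- list(params = params[params$date %in% days, ],
                states = data.frame(timestamp = ts, state = x, temp = temp,
                                    par = par))
  list(series = series, truth = truth)
}

#' Specification of sensor artifacts to inject
#'
#' Emulates the failure modes seen in field deployments: storm clogging
#' (DO pinned near zero), isolated single-sample spikes, slow biofouling
#' drift, and white-noise bursts that destroy the diel shape.
#'
#' @param clogs data.frame with POSIXct `start`, `end`: intervals during
#'   which the sensor reads uniform(0, 0.2) mg L^-1.
#' @param spike_rate Expected single-point anomalies per day.
#' @param spike_mag Range of spike magnitudes, mg L^-1 (sign randomised).
#' @param drifts data.frame `start`, `end`, `rate` (mg L^-1 d^-1): linear
#'   offset accumulating over the interval.
#' @param bursts data.frame `start`, `end`, `sd`: samples replaced by the
#'   interval mean plus white noise of the given sd.
#' @return List of class `artifact_spec`.
#' @export
artifact_spec <- function(clogs = NULL, spike_rate = 0, spike_mag = c(2, 4),
                          drifts = NULL, bursts = NULL) {
  chk <- function(x, extra = character()) {
    if (is.null(x)) return(NULL)
    stopifnot(is.data.frame(x), all(c("start", "end", extra) %in% names(x)))
    if (any(as.numeric(x$end) < as.numeric(x$start))) stop("interval end < start")
    x
  }
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  if (any(!is.finite(spike_mag)) || any(spike_mag <= 0))
    stop("spike magnitudes must be finite and positive")
  if (!is.null(drifts) && any(!is.finite(drifts$rate)))
    stop("drift rates must be finite")
  structure(list(clogs = chk(clogs), spike_rate = spike_rate,
                 spike_mag = sort(spike_mag), drifts = chk(drifts, "rate"),
                 bursts = chk(bursts, "sd")),
            class = "artifact_spec")
}

#' Corrupt a clean series with specified sensor artifacts
#'
#' Returns the corrupted copy together with a ledger indexing every modified
#' sample (type, timestamp, true and corrupted value), enabling exact
#' recall/precision scoring of the QAQC rules. Flags are left untouched:
#' detecting the corruption is the QAQC module's job.
#'
#' @param series A clean [do_series()].
#' @param spec An [artifact_spec()].
#' @param seed RNG seed; identical seeds reproduce the corruption exactly.
#' @return List with `series` (corrupted) and `ledger` (data.frame).
#' @export
inject_artifacts <- function(series, spec, seed = 1) {
  stopifnot(inherits(spec, "artifact_spec"))
  set.seed(seed)
  ts <- series$timestamp
  rng <- range(ts)
  in_interval <- function(tab, i) {
    ts[i] >= tab$start & ts[i] <= tab$end
  }
  sel_idx <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(list())
    lapply(seq_len(nrow(tab)), function(r) {
      if (tab$start[r] < rng[1] || tab$end[r] > rng[2])
        stop("artifact interval outside the simulated range")
      which(ts >= tab$start[r] & ts <= tab$end[r])
    })
  }
  clog_i <- sel_idx(spec$clogs)
  drift_i <- sel_idx(spec$drifts)
  burst_i <- sel_idx(spec$bursts)
  all_int <- c(clog_i, drift_i, burst_i)
  if (length(all_int) > 1) {
    for (p in seq_along(all_int)) for (q in seq_len(p - 1)) {
      if (length(intersect(all_int[[p]], all_int[[q]])))
        stop("overlapping contradictory artifacts")
    }
  }
  do <- series$do
  led <- list()
  note <- function(type, idx, new) {
    data.frame(type = type, timestamp = ts[idx], true_do = series$do[idx],
               corrupted_do = new, stringsAsFactors = FALSE)
  }
  if (!is.null(spec$drifts)) for (r in seq_along(drift_i)) {
    idx <- drift_i[[r]]
    off <- spec$drifts$rate[r] *
      as.numeric(ts[idx] - spec$drifts$start[r], units = "days")
    do[idx] <- do[idx] + off
    led[[length(led) + 1]] <- note("drift", idx, do[idx])
  }
  if (!is.null(spec$bursts)) for (r in seq_along(burst_i)) {
    idx <- burst_i[[r]]
    do[idx] <- pmax(mean(series$do[idx]) +
                      stats::rnorm(length(idx), 0, spec$bursts$sd[r]), 0)
    led[[length(led) + 1]] <- note("burst", idx, do[idx])
  }
  if (!is.null(spec$clogs)) for (r in seq_along(clog_i)) {
    idx <- clog_i[[r]]
    do[idx] <- stats::runif(length(idx), 0, 0.2)
    led[[length(led) + 1]] <- note("clog", idx, do[idx])
  }
  if (spec$spike_rate > 0) {
    n_days <- as.numeric(diff(rng), units = "days")
    n_spk <- stats::rpois(1, spec$spike_rate * n_days)
    taken <- unique(unlist(all_int))
    pool <- setdiff(seq(2, length(ts) - 1), taken)
    n_spk <- min(n_spk, length(pool))
    if (n_spk > 0) {
      idx <- sort(sample(pool, n_spk))
      mag <- sample(c(-1, 1), n_spk, replace = TRUE) *
        stats::runif(n_spk, spec$spike_mag[1], spec$spike_mag[2])
      do[idx] <- pmax(do[idx] + mag, 0)
      led[[length(led) + 1]] <- note("spike", idx, do[idx])
    }
  }
  ledger <- if (length(led)) do.call(rbind, led) else
    data.frame(type = character(), timestamp = ts[0], true_do = numeric(),
               corrupted_do = numeric())
  out <- series
  out$do <- do
  list(series = rebuild_series(out, series), ledger = ledger)
}

#' Build a paired upstream/downstream network scenario
#'
#' Constructs site pairs bracketing hypothetical wastewater treatment plant
#' outfalls in which every downstream day's GPP and |ER| are a fixed
#' multiple of the upstream day's, enabling end-to-end recovery tests of
#' the amplification statistics. K600 is constant per site (drawn once),
#' mimicking reach-controlled gas exchange.
#'
#' @param n_pairs Number of upstream/downstream pairs (>= 1).
#' @param factor_gpp,factor_er Downstream/upstream amplification factors
#'   (> 0). Defaults are the spring-time effect sizes typical of
#'   effluent-dominated reaches.
#' @param start,end Simulated date range.
#' @param seed RNG seed.
#' @param gpp_range,er_range Upstream daily parameter ranges.
#' @param k600_range Per-site K600 draw range, d^-1.
#' @param storms Optional shared storm calendar (data.frame start, end).
#' @return List of class `network_scenario` with `sites` (site table),
#'   `params` (named list of [true_day_params()] per site id), `factors`
#'   and `storms`.
#' @export
make_network_scenario <- function(n_pairs = 1, factor_gpp = 3.2,
                                  factor_er = 3.8, start = "2018-03-01",
                                  end = "2018-04-29", seed = 1,
                                  gpp_range = c(1.5, 3),
                                  er_range = c(-4.5, -2.5),
                                  k600_range = c(4, 12), storms = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (factor_gpp <= 0 || factor_er <= 0) stop("amplification factors must be > 0")
  set.seed(seed)
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  sites <- list(); params <- list()
  for (j in seq_len(n_pairs)) {
    plant <- LETTERS[j]
    d_up <- (j - 1) * 10
    d_dn <- d_up + 1.4
    id_up <- sprintf("U-%s-%g", plant, d_up)
    id_dn <- sprintf("D-%s-%g", plant, d_dn)
    up <- draw_day_params(dates, gpp_range = gpp_range, er_range = er_range,
                          k600_range = k600_range)
    up$k600 <- stats::runif(1, k600_range[1], k600_range[2])
    dn <- true_day_params(dates, gpp = up$gpp * factor_gpp,
                          er = up$er * factor_er,
                          k600 = stats::runif(1, k600_range[1], k600_range[2]))
    sites[[length(sites) + 1]] <- data.frame(
      id = c(id_up, id_dn), latitude = 40.19 - 0.01 * c(d_up, d_dn),
      longitude = -75.28, distance_km = c(d_up, d_dn),
      role = c("upstream", "downstream"), plant = plant, pair = j,
      stringsAsFactors = FALSE)
    params[[id_up]] <- up
    params[[id_dn]] <- dn
  }
  structure(list(sites = do.call(rbind, sites), params = params,
                 factors = c(gpp = factor_gpp, er = factor_er),
                 start = as.Date(start), end = as.Date(end),
                 storms = storms),
            class = "network_scenario")
}

#' Simulate sensor series for every site of a network scenario
#'
#' @param scenario A [make_network_scenario()] result.
#' @param config A [sim_config()] template; its date range is overridden by
#'   the scenario's and its seed is offset per site for independence.
#' @return Named list (by site id) of [simulate_do_series()] results.
#' @export
simulate_scenario <- function(scenario, config = NULL) {
  stopifnot(inherits(scenario, "network_scenario"))
  if (is.null(config)) config <- sim_config(scenario$start, scenario$end)
  config$start <- scenario$start
  config$end <- scenario$end
  out <- list()
  for (i in seq_along(scenario$params)) {
    cfg <- config
    cfg$seed <- config$seed + i
    id <- names(scenario$params)[i]
    cfg$latitude <- scenario$sites$latitude[scenario$sites$id == id]
    cfg$longitude <- scenario$sites$longitude[scenario$sites$id == id]
    sim <- simulate_do_series(scenario$params[[i]], cfg)
    attr(sim$series, "site_id") <- id
    out[[id]] <- sim
  }
  out
}
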