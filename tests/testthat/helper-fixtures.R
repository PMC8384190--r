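# shared fixture builders and independent oracles

TZ <- "Etc/GMT+5"

day_grid <- function(date = "2017-06-01", dt_min = 15, tz = TZ) {
  seq(as.POSIXct(paste(date, "00:00:00"), tz = tz),
      as.POSIXct(paste(date, "23:59:59"), tz = tz), by = dt_min * 60)
}

# one clean simulated day as a do_series plus its truth
sim_one_day <- function(gpp = 5, er = -6, k600 = 8, depth = 0.3,
                        sigma_obs = 0.2, sigma_proc = 0.05, seed = 42,
                        date = "2017-06-01") {
  cfg <- sim_config(date, date, depth = depth, sigma_obs = sigma_obs,
                    sigma_proc = sigma_proc, seed = seed)
  p <- true_day_params(as.Date(date), gpp = gpp, er = er, k600 = k600)
  simulate_do_series(p, cfg)
}

# independent fine-grid explicit-Euler integration of the oxygen balance:
# dO/dt = (gpp/z) f(t) + er/z + kO2(t) (Osat(T) - O). The light allocation
# is the same piecewise-constant per-coarse-step fraction the model uses
# (each fine step inside coarse step i receives an equal share of w_i), so
# the comparison isolates the time-integration scheme.
euler_oracle <- function(gpp, er, k600, depth, timestamps, latitude,
                         longitude, temp_fun, o0, dt_fine_min = 1) {
  t0 <- timestamps[1]
  tn <- timestamps[length(timestamps)]
  fine <- seq(t0, tn, by = dt_fine_min * 60)
  temp <- temp_fun(fine)
  coarse_par <- modeled_par(timestamps, latitude, longitude)$par
  w <- light_fractions(coarse_par[-length(coarse_par)])
  # parent coarse transition of each fine transition
  parent <- findInterval(as.numeric(fine[-length(fine)]),
                         as.numeric(timestamps))
  per_fine <- as.numeric(table(factor(parent, levels = seq_along(w))))
  frac <- w[parent] / per_fine[parent]
  osat <- o2_saturation(temp)
  ko2 <- k600_to_ko2(k600, temp)
  dt_days <- dt_fine_min / (24 * 60)
  x <- numeric(length(fine))
  x[1] <- o0
  for (i in seq_len(length(fine) - 1)) {
    x[i + 1] <- x[i] + gpp / depth * frac[i] + er / depth * dt_days +
      ko2[i] * dt_days * (osat[i] - x[i])
  }
  x[match(as.numeric(timestamps), as.numeric(fine))]
}

# brute-force window enumeration: all size-n subsets that are contiguous in
# the sorted day list with adjacent gaps <= max_gap
brute_force_windows <- function(days, n, max_gap = 3) {
  days <- sort(unique(as.Date(days)))
  if (length(days) < n) return(list())
  combos <- utils::combn(seq_along(days), n, simplify = FALSE)
  keep <- Filter(function(ix) {
    all(diff(ix) == 1) && all(diff(as.numeric(days[ix])) <= max_gap)
  }, combos)
  lapply(keep, function(ix) days[ix])
}

# exact two-group permutation p-value for the Kruskal-Wallis statistic
exact_kw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  H_obs <- kruskal_wallis(pooled, rep(1:2, c(length(a), length(b))))$statistic
  idx <- utils::combn(n, length(a), simplify = FALSE)
  hs <- vapply(idx, function(ix) {
    kruskal_wallis(pooled, replace(rep(2, n), ix, 1))$statistic
  }, numeric(1))
  mean(hs >= H_obs - 1e-12)
}
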