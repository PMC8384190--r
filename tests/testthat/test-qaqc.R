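mk_series <- function(do, date = "2017-06-01", temp = 20, depth = 0.3,
                      qc = "ok") {
  ts <- day_grid(date)[seq_along(do)]
  do_series(ts, do = do, temp = temp, depth = depth, qc = qc,
            latitude = 40.19, longitude = -75.28)
}

sine_day <- function(amp = 2, level = 8, n = 96, noise = 0, seed = 1) {
  set.seed(seed)
  h <- (seq_len(n) - 1) / 4
  level + amp / 2 * sin(2 * pi * (h - 10) / 24) + rnorm(n, 0, noise)
}

all_day_storm <- function(date = "2017-06-01") {
  data.frame(start = as.POSIXct(paste(date, "00:00:00"), tz = TZ),
             end = as.POSIXct(paste(date, "23:59:59"), tz = TZ))
}

test_that("clog flagging is confined to storm intervals", {
  x <- sine_day()
  x[40:47] <- 0.05
  s <- mk_series(x)
  # no storm declared: the clog rule must not fire
  cfg0 <- qaqc_config(storms = dielmetab:::empty_storms())
  expect_true(all(flag_storm_clogging(s, cfg0)$qc == "ok"))
  # storm covering the clog: exactly those samples flagged
  cfg <- qaqc_config(storms = all_day_storm())
  out <- flag_storm_clogging(s, cfg)
  expect_equal(which(out$qc == "removed_clog"), 40:47)
  # clean day inside a storm: nothing flagged
  expect_true(all(flag_storm_clogging(mk_series(sine_day()), cfg)$qc == "ok"))
})

test_that("storm-day removal needs both a storm and an abrupt step", {
  step_day <- sine_day()
  step_day[49:96] <- step_day[49:96] + 3 # instantaneous 3 mg/L shift
  storm <- qaqc_config(storms = all_day_storm())
  nostorm <- qaqc_config(storms = dielmetab:::empty_storms())
  expect_true(all(remove_storm_disrupted_days(mk_series(step_day),
                                              storm)$qc ==
                    "removed_storm_day"))
  # same step without a storm: retained by this rule
  expect_true(all(remove_storm_disrupted_days(mk_series(step_day),
                                              nostorm)$qc == "ok"))
  # smooth sine inside a storm: retained
  expect_true(all(remove_storm_disrupted_days(mk_series(sine_day()),
                                              storm)$qc == "ok"))
})

test_that("despiking replaces isolated spikes by the neighbour mean", {
  # a realistic-length quiet day so the adaptive threshold reflects the
  # day's noise, with the canonical spike sequence embedded mid-day
  x <- c(seq(7.2, 7.9, by = 0.1), 8.0, 8.1, 12.0, 8.2, 8.3,
         seq(8.4, 9.1, by = 0.1))
  i_spike <- 11
  out <- despike_single_points(mk_series(x), qaqc_config())
  expect_equal(out$do[i_spike], 8.15) # (8.1 + 8.2) / 2
  expect_equal(out$qc[i_spike], "despiked")
  expect_equal(out$qc[-i_spike], rep("ok", length(x) - 1))
  # monotone ramp untouched
  ramp <- despike_single_points(mk_series(c(7, 8, 9, 10)), qaqc_config())
  expect_equal(ramp$do, c(7, 8, 9, 10))
  expect_true(all(ramp$qc == "ok"))
  # two adjacent anomalies are not single-point spikes
  x2 <- c(8.0, 8.1, 12.0, 12.1, 8.2, 8.3)
  out2 <- despike_single_points(mk_series(x2), qaqc_config())
  expect_equal(out2$do, x2)
})

test_that("three-point smoothing averages interior points of noisy diel days", {
  # eligible day: clear diel signal with heavy measurement noise
  noisy <- sine_day(amp = 4, noise = 0.6, seed = 3)
  sm <- smooth_three_point(mk_series(noisy), qaqc_config())
  expect_gt(sm$n_days, 0)
  i <- 50
  expect_equal(sm$series$do[i], mean(noisy[(i - 1):(i + 1)]))
  expect_gt(sm$mean_change, 0)
  # constant series: nothing to do
  flat <- smooth_three_point(mk_series(rep(8, 96)), qaqc_config())
  expect_equal(flat$n_days, 0)
  expect_equal(flat$mean_change, 0)
  # clean low-noise day not selected
  clean <- smooth_three_point(mk_series(sine_day(noise = 0.1, seed = 4)),
                              qaqc_config())
  expect_equal(clean$n_days, 0)
})

test_that("diel signal assessment separates signal from noise", {
  ts <- day_grid()
  pure <- sine_day(amp = 2)
  sig <- assess_diel_signal(ts, pure)
  expect_true(sig$has_diel)
  expect_gt(sig$snr, 100)
  expect_equal(sig$amplitude, 1, tolerance = 0.01)
  set.seed(5)
  noise <- assess_diel_signal(ts, rnorm(96, 8, 0.5))
  expect_false(noise$has_diel)
  flat <- assess_diel_signal(ts, rep(8, 96))
  expect_false(flat$has_diel)
  # under half a day present: indeterminate
  part <- assess_diel_signal(ts[1:40], pure[1:40], expected = 96)
  expect_true(is.na(part$has_diel))
})

test_that("full QAQC is the identity on clean data and idempotent", {
  cfg <- sim_config("2017-06-01", "2017-06-20", seed = 12)
  p <- draw_day_params(seq(as.Date("2017-06-01"), as.Date("2017-06-20"),
                           by = "day"), gpp_range = c(2, 4),
                       er_range = c(-4.5, -2.5), k600_range = c(8, 8))
  ser <- simulate_do_series(p, cfg)$series
  res <- run_qaqc(ser)
  expect_true(all(res$series$qc == "ok"))
  expect_equal(res$report$fraction_days_removed, 0)
  # fixed point: rerunning on its own output changes nothing
  res2 <- run_qaqc(res$series)
  expect_identical(res2$series$do, res$series$do)
  expect_identical(res2$series$qc, res$series$qc)
})

test_that("QAQC never fabricates values outside its two defined replacements", {
  cfg <- sim_config("2017-06-01", "2017-06-10", seed = 13)
  p <- draw_day_params(seq(as.Date("2017-06-01"), as.Date("2017-06-10"),
                           by = "day"), gpp_range = c(2, 4),
                       er_range = c(-4.5, -2.5), k600_range = c(8, 8))
  ser <- simulate_do_series(p, cfg)$series
  spec <- artifact_spec(spike_rate = 2, spike_mag = c(2, 4))
  inj <- inject_artifacts(ser, spec, seed = 2)
  out <- run_qaqc(inj$series)$series
  altered <- out$do != inj$series$do
  expect_true(all(out$qc[altered] %in% c("despiked", "smoothed")))
})

test_that("drift detection recovers a ramp interval on stable data", {
  # constant metabolism, low noise: a biofouling ramp must be flagged over
  # (almost exactly) its injected extent and nowhere else
  cfg <- sim_config("2017-06-01", "2017-06-30", seed = 21, sigma_obs = 0.1,
                    sigma_proc = 0.02)
  p <- true_day_params(seq(as.Date("2017-06-01"), as.Date("2017-06-30"),
                           by = "day"), gpp = 3, er = -4, k600 = 8)
  ser <- simulate_do_series(p, cfg)$series
  spec <- artifact_spec(drifts = data.frame(
    start = as.POSIXct("2017-06-15 00:00:00", tz = TZ),
    end = as.POSIXct("2017-06-26 23:45:00", tz = TZ), rate = 0.5))
  inj <- inject_artifacts(ser, spec, seed = 3)
  out <- run_qaqc(inj$series)$series
  day <- dielmetab:::series_dates(out)
  flagged_days <- sort(unique(day[out$qc == "removed_drift"]))
  drift_days <- seq(as.Date("2017-06-15"), as.Date("2017-06-26"), by = "day")
  # no clean day flagged; at most the two onset days missed
  expect_true(all(flagged_days %in% drift_days))
  expect_gte(length(flagged_days), length(drift_days) - 2)
})
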