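test_that("zero metabolism at constant temperature stays at saturation", {
  cfg <- sim_config("2017-06-01", "2017-06-01", sigma_obs = 0, sigma_proc = 0,
                    temp_diel_amp = 0, temp_seasonal_amp = 0)
  p <- true_day_params(as.Date("2017-06-01"), gpp = 0, er = 0, k600 = 5)
  s <- simulate_do_series(p, cfg)
  expect_equal(s$series$do, o2_saturation(s$series$temp), tolerance = 1e-10)
})

test_that("pure respiration with no gas exchange integrates exactly", {
  # ER of -1 g O2 m^-2 d^-1 in 1 m of water removes 1 mg/L per 24 h
  cfg <- sim_config("2017-06-01", "2017-06-02", sigma_obs = 0,
                    sigma_proc = 0, depth = 1, temp_diel_amp = 0,
                    temp_seasonal_amp = 0, do_init = 9)
  p <- true_day_params(seq(as.Date("2017-06-01"), as.Date("2017-06-02"),
                           by = "day"), gpp = 0, er = -1, k600 = 0)
  s <- simulate_do_series(p, cfg)
  i24 <- 1 + 24 * 4 # same clock time one day later
  expect_equal(s$series$do[1] - s$series$do[i24], 1.0, tolerance = 1e-9)
})

test_that("noiseless 15-min simulation matches a 1-min Euler oracle", {
  cfg <- sim_config("2017-06-01", "2017-06-01", sigma_obs = 0,
                    sigma_proc = 0, depth = 0.3)
  p <- true_day_params(as.Date("2017-06-01"), gpp = 5, er = -6, k600 = 8)
  s <- simulate_do_series(p, cfg)
  oracle <- euler_oracle(5, -6, 8, 0.3, s$series$timestamp, cfg$latitude,
                         cfg$longitude,
                         temp_fun = function(ts) {
                           dielmetab:::sim_temperature(ts, cfg)
                         },
                         o0 = s$series$do[1])
  expect_lt(max(abs(s$series$do - oracle)), 0.05)
})

test_that("relaxation toward saturation is monotone from any start", {
  for (o0 in c(2, 14)) {
    cfg <- sim_config("2017-06-01", "2017-06-01", sigma_obs = 0,
                      sigma_proc = 0, temp_diel_amp = 0,
                      temp_seasonal_amp = 0, do_init = o0)
    p <- true_day_params(as.Date("2017-06-01"), gpp = 0, er = 0, k600 = 10)
    do <- simulate_do_series(p, cfg)$series$do
    gap <- abs(do - o2_saturation(cfg$temp_mean))
    expect_true(all(diff(gap) <= 1e-12))
  }
})

test_that("seeded simulation is bit-reproducible", {
  cfg <- sim_config("2017-06-01", "2017-06-03", seed = 7)
  p <- true_day_params(seq(as.Date("2017-06-01"), as.Date("2017-06-03"),
                           by = "day"), gpp = 4, er = -5, k600 = 8)
  expect_identical(simulate_do_series(p, cfg), simulate_do_series(p, cfg))
})

test_that("missing day parameters are reported by date", {
  cfg <- sim_config("2017-06-01", "2017-06-03")
  p <- true_day_params(as.Date(c("2017-06-01", "2017-06-03")),
                       gpp = 4, er = -5, k600 = 8)
  expect_error(simulate_do_series(p, cfg), "2017-06-02")
})

test_that("artifact injection is exact, ledgered and reproducible", {
  cfg <- sim_config("2017-06-01", "2017-06-10", seed = 3)
  p <- draw_day_params(seq(as.Date("2017-06-01"), as.Date("2017-06-10"),
                           by = "day"))
  ser <- simulate_do_series(p, cfg)$series

  # empty spec: identity
  empty <- inject_artifacts(ser, artifact_spec(), seed = 1)
  expect_identical(empty$series$do, ser$do)
  expect_equal(nrow(empty$ledger), 0)

  # a 2 h clog touches exactly ceil(120 / 15) = 8 grid samples
  clog <- artifact_spec(clogs = data.frame(
    start = as.POSIXct("2017-06-02 08:00:00", tz = TZ),
    end = as.POSIXct("2017-06-02 09:59:00", tz = TZ)))
  out <- inject_artifacts(ser, clog, seed = 1)
  expect_equal(nrow(out$ledger), 8)
  expect_true(all(out$series$do[match(as.numeric(out$ledger$timestamp),
                                      as.numeric(ser$timestamp))] < 0.2))

  # the ledger indexes every modified sample, and only those
  spec <- artifact_spec(clogs = clog$clogs, spike_rate = 1,
                        drifts = data.frame(
                          start = as.POSIXct("2017-06-05 00:00:00", tz = TZ),
                          end = as.POSIXct("2017-06-07 23:45:00", tz = TZ),
                          rate = 0.5))
  out2 <- inject_artifacts(ser, spec, seed = 9)
  changed <- which(out2$series$do != ser$do)
  led_idx <- sort(match(as.numeric(out2$ledger$timestamp),
                        as.numeric(ser$timestamp)))
  expect_true(all(changed %in% led_idx))

  # seeded rerun reproduces the Poisson spike draw exactly
  out3 <- inject_artifacts(ser, spec, seed = 9)
  expect_identical(out2$ledger, out3$ledger)
  n_spikes <- sum(out2$ledger$type == "spike")
  expect_gte(n_spikes, 0)

  # contradictory overlap rejected
  bad <- artifact_spec(clogs = clog$clogs,
                       bursts = data.frame(
                         start = as.POSIXct("2017-06-02 09:00:00", tz = TZ),
                         end = as.POSIXct("2017-06-02 12:00:00", tz = TZ),
                         sd = 1))
  expect_error(inject_artifacts(ser, bad, seed = 1), "overlapping")

  # interval outside the simulated range rejected
  outside <- artifact_spec(clogs = data.frame(
    start = as.POSIXct("2017-07-01 00:00:00", tz = TZ),
    end = as.POSIXct("2017-07-01 02:00:00", tz = TZ)))
  expect_error(inject_artifacts(ser, outside, seed = 1), "range")
})

test_that("network scenarios encode amplification by construction", {
  sc <- make_network_scenario(2, factor_gpp = 3.2, factor_er = 3.8,
                              start = "2018-03-01", end = "2018-04-29",
                              seed = 5)
  for (j in 1:2) {
    ids <- sc$sites$id[sc$sites$pair == j]
    up <- sc$params[[ids[grepl("^U", ids)]]]
    dn <- sc$params[[ids[grepl("^D", ids)]]]
    expect_equal(dn$gpp / up$gpp, rep(3.2, nrow(up)))
    expect_equal(dn$er / up$er, rep(3.8, nrow(up)))
  }
  # identity factors give identical metabolic sequences
  sc1 <- make_network_scenario(1, 1, 1, seed = 2)
  ids <- sc1$sites$id
  expect_equal(sc1$params[[ids[1]]]$gpp, sc1$params[[ids[2]]]$gpp)
  # determinism
  expect_identical(make_network_scenario(2, seed = 5),
                   make_network_scenario(2, seed = 5))
  expect_error(make_network_scenario(0), "n_pairs")
  expect_error(make_network_scenario(1, factor_gpp = -1), "factor")
})

test_that("daily parameter draws span their ranges with uniform marginals", {
  set.seed(1)
  d <- seq(as.Date("2017-01-01"), by = "day", length.out = 400)
  p <- draw_day_params(d)
  expect_true(all(p$gpp >= 2 & p$gpp <= 8))
  expect_true(all(p$er >= -11 & p$er <= -3))
  expect_true(all(p$k600 >= 4 & p$k600 <= 12))
  # persistence: adjacent days are positively correlated
  expect_gt(cor(p$gpp[-1], p$gpp[-400]), 0.5)
  # rho = 0 gives independent days
  set.seed(2)
  p0 <- draw_day_params(d, rho = 0)
  expect_lt(abs(cor(p0$gpp[-1], p0$gpp[-400])), 0.15)
})
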