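mk_metrics <- function(dates, mins, means = NULL) {
  if (is.null(means)) means <- mins + 2
  data.frame(date = as.Date(dates), mean = means, min = mins,
             max = means + 2, amplitude = 4, coverage = 1)
}

test_that("daily metrics summarise usable samples with a coverage gate", {
  ts <- day_grid("2017-06-01")
  flat <- do_series(ts, do = 8, temp = 20, qc = "ok")
  m <- daily_metrics(flat, coverage = 0.8)
  expect_equal(m$mean, 8)
  expect_equal(m$min, 8)
  expect_equal(m$amplitude, 0)
  # sinusoid 7 +/- 2: min 5, max 9 at the grid resolution
  h <- (seq_along(ts) - 1) / 4
  sine <- do_series(ts, do = 7 + 2 * sin(2 * pi * h / 24), temp = 20)
  ms <- daily_metrics(sine, coverage = 0.8)
  expect_equal(ms$min, 5, tolerance = 0.01)
  expect_equal(ms$max, 9, tolerance = 0.01)
  expect_equal(ms$amplitude, 4, tolerance = 0.02)
  # a 40%-coverage day is omitted and logged
  part <- do_series(ts, do = 8, temp = 20,
                    qc = rep(c("ok", "missing"), c(38, 58)))
  mp <- daily_metrics(part, coverage = 0.8)
  expect_equal(nrow(mp), 0)
  expect_equal(length(attr(mp, "omitted")), 1)
})

test_that("window enumeration reproduces the worked example", {
  days <- as.Date(c("2018-03-13", "2018-03-15", "2018-03-18",
                    "2018-03-19", "2018-03-22"))
  w <- enumerate_windows(days, 3, max_gap = 3)
  expect_equal(length(w), 3)
  expect_equal(vapply(w, function(x) format(x[1]), ""),
               c("2018-03-13", "2018-03-15", "2018-03-18"))
  # five truly consecutive days: 3 windows of length 3
  expect_equal(length(enumerate_windows(as.Date("2018-04-01") + 0:4, 3)), 3)
  # gap-free record of D days: D - N + 1 windows
  expect_equal(length(enumerate_windows(as.Date("2018-04-01") + 0:29, 7)),
               24)
  expect_equal(enumerate_windows(as.Date("2018-04-01") + c(0, 10), 2), list())
})

test_that("window enumeration equals brute force on random day sets", {
  set.seed(15)
  for (rep in 1:20) {
    days <- as.Date("2018-03-01") + sort(sample(0:29, sample(5:18, 1)))
    n <- sample(2:5, 1)
    fast <- enumerate_windows(days, n, max_gap = 3)
    brute <- brute_force_windows(days, n, max_gap = 3)
    expect_equal(fast, brute)
  }
})

test_that("window statistics apply strict-inequality criteria", {
  m <- mk_metrics(as.Date("2018-04-01") + 0:2, mins = c(5.2, 4.6, 4.9),
                  means = c(8, 8, 8))
  w <- window_stats(as.Date("2018-04-01") + 0:2, m)
  expect_equal(w$window_mean_min, 4.9)
  expect_true(w$epa_min) # 4.9 < 5
  expect_false(w$padep_mean)
  # boundary: exactly 6.0 is NOT a violation
  m6 <- mk_metrics(as.Date("2018-04-01") + 0:2, mins = c(6, 6, 6),
                   means = c(6, 6, 6))
  w6 <- window_stats(as.Date("2018-04-01") + 0:2, m6)
  expect_false(w6$padep_mean)
  expect_false(w6$epa_min)
  # missing member metrics: window dropped
  expect_null(window_stats(as.Date("2018-04-01") + 0:3, m))
})

test_that("longer averaging windows dilute a short hypoxic dip", {
  dates <- as.Date("2018-04-01") + 0:59
  mins <- rep(7, 60); mins[25:29] <- 4 # 5-day dip
  m <- mk_metrics(dates, mins, means = mins + 2)
  v <- count_violations(m, lengths = c(3, 30))
  v3 <- v$epa_min[v$length == 3]
  v30 <- v$epa_min[v$length == 30]
  expect_gt(v3, 0)
  expect_gt(v3, v30)
  # an always-oxygenated site never violates
  ok <- count_violations(mk_metrics(dates, rep(8, 60)),
                         lengths = c(3, 7, 15, 30))
  expect_true(all(ok$padep_mean == 0))
  expect_true(all(ok$epa_min == 0))
  expect_true(all(ok$n_windows == c(58, 54, 46, 31)))
})

test_that("violation counts can be re-verified from raw daily metrics", {
  set.seed(16)
  dates <- as.Date("2018-04-01") + sort(sample(0:49, 35))
  m <- mk_metrics(dates, mins = runif(35, 4, 7))
  v <- count_violations(m, lengths = 7)
  wins <- enumerate_windows(m$date, 7, 3)
  audit <- sum(vapply(wins, function(w) {
    mean(m$min[match(as.character(w), as.character(m$date))]) < 5
  }, logical(1)))
  expect_equal(v$epa_min, audit)
  expect_equal(v$n_windows, length(wins))
})

test_that("single-day violation capture follows the binomial expectation", {
  set.seed(17)
  n_days <- 307
  dates <- as.Date("2017-04-01") + 0:(n_days - 1)
  viol <- sample(n_days, 59)
  mins <- rep(7, n_days); mins[viol] <- 4.5
  m <- mk_metrics(dates, mins)
  s <- single_day_violations(m, threshold = 5, lengths = c(7, 15, 30))
  expect_equal(s$n_violation_days, 59)
  cap30 <- s$capture[s$capture$length == 30, ]
  expected <- 30 * 59 / 307
  expect_lte(cap30$q25, expected)
  expect_gte(cap30$q75, expected)
  expect_lte(cap30$max, 30)
  # capture counts grow with window length (nested windows, same start)
  expect_lte(s$capture$median[1], s$capture$median[3])
  # no violations: degenerate capture distribution at zero
  s0 <- single_day_violations(mk_metrics(dates, rep(8, n_days)))
  expect_equal(s0$n_violation_days, 0)
  expect_true(all(s0$capture$max == 0))
})
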