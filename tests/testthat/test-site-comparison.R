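test_that("Kruskal-Wallis matches the hand rank-sum formula and conventions", {
  # two separated groups of 3: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-9)
  expect_equal(kw$direction, "higher")
  # identical groups: no signal
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(same$statistic, 1e-9)
  expect_equal(same$class, "ns")
  # all values tied: H = 0, p = 1 by convention
  tied <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "groups")
})

test_that("Kruskal-Wallis p is close to the exact permutation law at small n", {
  set.seed(4)
  for (rep in 1:3) {
    a <- round(rnorm(4, 10, 2), 2)
    b <- round(rnorm(4, 12, 2), 2)
    p_chisq <- kruskal_wallis(c(a, b), rep(1:2, each = 4))$p
    p_exact <- exact_kw_p(a, b)
    expect_lt(abs(p_chisq - p_exact), 0.11)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(6)
  x <- rexp(20) + 1
  g <- rep(c("u", "d"), 10)
  h0 <- kruskal_wallis(x, g)
  for (f in list(log, sqrt, function(v) v^3)) {
    expect_equal(kruskal_wallis(f(x), g)$statistic, h0$statistic,
                 tolerance = 1e-12)
  }
})

test_that("significance classes follow the star convention", {
  expect_equal(significance_class(c(5e-4, 5e-3, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
})

test_that("day pairing is the date intersection", {
  up <- data.frame(date = as.Date("2018-03-01") + c(0, 1, 2), gpp = 1:3)
  down <- data.frame(date = as.Date("2018-03-01") + c(1, 2, 3), gpp = 4:6)
  pr <- paired_days(up, down)
  expect_equal(pr$date, as.Date("2018-03-01") + c(1, 2))
  expect_equal(pr$gpp_up, 2:3)
  expect_equal(pr$gpp_down, 4:5)
  expect_warning(paired_days(up, data.frame(date = as.Date("2019-01-01"),
                                            gpp = 1)), "shared")
  # identical date sets pair completely
  expect_equal(nrow(paired_days(up, up)), 3)
})

test_that("amplification summaries follow their two estimators", {
  pr <- data.frame(date = as.Date("2018-03-01") + 0:2,
                   gpp_up = c(2, 2, 2), gpp_down = c(4, 6, 8),
                   er_up = c(-2, -2, -2), er_down = c(-4, -6, -8))
  a <- amplification(pr, "gpp")
  expect_equal(a$mean_ratio, 3)
  expect_equal(a$se_ratio, sd(c(2, 3, 4)) / sqrt(3))
  expect_equal(a$median_ratio, 3)
  # ER uses magnitudes so ratios stay positive
  e <- amplification(pr, "er")
  expect_equal(e$mean_ratio, 3)
  # self-comparison is exactly 1 on every day
  self <- data.frame(date = pr$date, gpp_up = c(2, 5, 7),
                     gpp_down = c(2, 5, 7))
  expect_equal(amplification(self, "gpp")$mean_ratio, 1)
  expect_equal(amplification(self, "gpp")$se_ratio, 0)
  # zero upstream days are excluded and counted
  z <- data.frame(date = pr$date, gpp_up = c(0, 2, 2), gpp_down = c(1, 4, 6))
  az <- amplification(z, "gpp")
  expect_equal(az$n, 2)
  expect_equal(az$n_excluded, 1)
  expect_equal(az$mean_ratio, 2.5)
})

test_that("the pairwise site matrix is symmetric with directional encoding", {
  set.seed(8)
  sites <- list(a = rnorm(30, 5), b = rnorm(30, 5), c = rnorm(30, 10, 0.5))
  m <- pairwise_site_matrix(sites)
  expect_true(is.na(m$p["a", "a"]))
  expect_equal(m$p["a", "b"], m$p["b", "a"])
  # medians differing by many sd: highly significant
  expect_equal(m$class["a", "c"], "***")
  expect_equal(m$direction["c", "a"], "higher")
  expect_equal(m$direction["a", "c"], "lower")
  # a site with no data leaves its row indeterminate
  m2 <- pairwise_site_matrix(list(a = rnorm(10), b = numeric(0)))
  expect_true(is.na(m2$p["a", "b"]))
})

test_that("pairwise tests are calibrated under a shared null", {
  set.seed(11)
  sites <- setNames(lapply(1:8, function(i) rnorm(40, 5, 1)),
                    paste0("s", 1:8))
  m <- pairwise_site_matrix(sites)
  frac_sig <- mean(m$p[upper.tri(m$p)] < 0.05)
  expect_lt(frac_sig, 0.2) # ~alpha, with Monte-Carlo slack
})

test_that("Pearson r and OLS agree and reproduce the published values", {
  tab <- wissahickon_annual_metabolism()
  sites <- wissahickon_sites()
  d <- sites$distance_km[match(tab$site, sites$site)]
  expect_equal(round(pearson_r(d, tab$gpp), 3), 0.016, tolerance = 1e-8)
  expect_equal(round(pearson_r(d, tab$er), 3), 0.156, tolerance = 1e-8)
  reg <- ols_regression(tab$gpp, tab$er)
  expect_equal(round(reg$r_squared, 2), 0.92, tolerance = 1e-8)
  # R^2 = r^2 on the same bivariate data
  expect_equal(reg$r_squared, pearson_r(tab$gpp, tab$er)^2,
               tolerance = 1e-12)
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
  expect_error(ols_regression(rep(1, 5), 1:5), "constant")
})

test_that("OLS recovers a known slope within its confidence interval", {
  set.seed(13)
  x <- runif(50)
  y <- 2 * x + rnorm(50, 0, 0.1)
  reg <- ols_regression(x, y)
  expect_lt(abs(reg$slope - 2), 2.01 * reg$slope_se)
  expect_lt(reg$p, 1e-10)
  # perfect collinearity (lm warns about the perfect fit, which is the point)
  expect_equal(suppressWarnings(ols_regression(1:10, 3 * (1:10) - 2)$r_squared),
               1)
})

test_that("metabolic fingerprints are normalised with a tie-aware autotrophy rule", {
  set.seed(14)
  gpp <- rnorm(60, 5, 0.3)
  er <- rnorm(60, -4, 0.3)
  fp <- metabolic_fingerprint(gpp, er)
  dx <- diff(fp$x[1:2]); dy <- diff(fp$y[1:2])
  expect_equal(sum(fp$z) * dx * dy, 1, tolerance = 0.01)
  expect_equal(unname(fp$median["gpp"]), median(gpp))
  # tight cluster: median point at the cluster centre within the grid
  expect_lt(abs(fp$median["gpp"] - 5), 0.2)
  # mostly autotrophic sample
  expect_gt(fp$autotrophy_fraction, 0.9)
  # days exactly on the 1:1 line are not autotrophic
  on_line <- metabolic_fingerprint(c(1, 2, 3, 4, 5), -c(1, 2, 3, 4, 5))
  expect_equal(on_line$autotrophy_fraction, 0)
  expect_error(metabolic_fingerprint(1:4, -(1:4)), "5")
})

test_that("site ids parse into role, plant and distance", {
  p <- parse_site_id(c("U-A-0", "D-B-14.5", "D-All-33.5"))
  expect_equal(p$role, c("upstream", "downstream", "downstream"))
  expect_equal(p$plant, c("A", "B", "All"))
  expect_equal(p$distance_km, c(0, 14.5, 33.5))
  expect_error(parse_site_id("X-A-1"), "role")
})
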