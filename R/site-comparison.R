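#' Significance class of a p-value
#'
#' Star convention: p < 0.001 highly significant (***), 0.001 <= p < 0.01
#' moderately (**), 0.01 <= p < 0.05 weakly (*), else ns.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Character vector in {"***", "**", "*", "ns"}.
#' @export
significance_class <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Kruskal-Wallis rank-sum test with direction and star class
#'
#' Wraps [stats::kruskal.test()] (tie-corrected H, chi-square p on k - 1
#' df) and adds the direction of the difference (sign of the median of the
#' last group minus the first) plus the significance class. Identical
#' values across all groups yield H = 0, p = 1 by convention.
#'
#' @param values Numeric observations, pooled.
#' @param groups Group labels, same length (>= 2 groups).
#' @return List of class `kw_test`: `statistic`, `df`, `p`, `direction`
#'   ("higher", "lower" or "equal": last group's median vs the first's),
#'   `class`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (length(values) < 3) stop("need total n >= 3")
  meds <- tapply(values, groups, stats::median)
  if (stats::var(values) < 1e-24 || length(unique(values)) == 1) {
    res <- list(statistic = 0, df = nlevels(droplevels(groups)) - 1, p = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
    res <- list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                p = kw$p.value)
  }
  dm <- meds[length(meds)] - meds[1]
  res$direction <- if (dm > 0) "higher" else if (dm < 0) "lower" else "equal"
  res$class <- significance_class(res$p)
  class(res) <- "kw_test"
  res
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (%s), last group %s\n",
              x$statistic, x$df, x$p, x$class, x$direction))
  invisible(x)
}

#' Align two sites' daily estimates on shared days
#'
#' Upstream-downstream comparisons are constrained to days when both sites
#' have usable data; this returns the intersection by calendar date.
#'
#' @param up,down data.frames of daily estimates with a `date` column
#'   (already usability-filtered).
#' @return data.frame with `date` plus the two sites' columns suffixed
#'   `_up` / `_down`; empty (with a warning) if no dates are shared.
#' @export
paired_days <- function(up, down) {
  shared <- intersect(as.character(up$date), as.character(down$date))
  if (!length(shared)) {
    warning("no shared days between the two sites")
  }
  u <- up[match(shared, as.character(up$date)), , drop = FALSE]
  d <- down[match(shared, as.character(down$date)), , drop = FALSE]
  out <- data.frame(date = as.Date(shared))
  for (cc in setdiff(names(u), "date")) out[[paste0(cc, "_up")]] <- u[[cc]]
  for (cc in setdiff(names(d), "date")) out[[paste0(cc, "_down")]] <- d[[cc]]
  out
}

#' Downstream/upstream amplification of a metabolic rate
#'
#' For each paired day the daily ratio downstream/upstream is computed
#' (using |ER| for respiration so ratios are positive; direction is carried
#' by the sign convention of ER itself), then summarised per season as mean
#' +/- standard error of the daily ratios, together with the
#' ratio-of-medians estimator. Days with a zero upstream rate are excluded
#' from ratios and counted.
#'
#' @param pairs Output of [paired_days()].
#' @param rate "gpp" or "er".
#' @param calendar Optional season calendar ([classify_seasons()]); when
#'   NULL all days form a single "all" season.
#' @return data.frame with one row per season: `n`, `n_excluded`,
#'   `mean_ratio`, `se_ratio`, `median_ratio` (ratio of medians).
#' @export
amplification <- function(pairs, rate = c("gpp", "er"), calendar = NULL) {
  rate <- match.arg(rate)
  up <- pairs[[paste0(rate, "_up")]]
  down <- pairs[[paste0(rate, "_down")]]
  if (rate == "er") { up <- abs(up); down <- abs(down) }
  season <- if (is.null(calendar)) rep("all", nrow(pairs)) else
    season_of(pairs$date, calendar)
  out <- list()
  for (s in unique(season)) {
    sel <- season == s & !is.na(season)
    if (is.null(calendar)) sel <- rep(TRUE, nrow(pairs))
    u <- up[sel]; d <- down[sel]
    ok <- u != 0
    r <- d[ok] / u[ok]
    out[[s]] <- data.frame(
      season = s, n = sum(ok), n_excluded = sum(!ok),
      mean_ratio = mean(r),
      se_ratio = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0,
      median_ratio = stats::median(d[ok]) / stats::median(u[ok]),
      stringsAsFactors = FALSE)
    if (is.null(calendar)) break
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All-pairs Kruskal-Wallis comparison matrix across sites
#'
#' @param site_days Named list of numeric vectors (usable daily rates per
#'   site).
#' @return List with matrices `p`, `H`, `class` and `direction` (row site's
#'   median minus column site's, encoded "higher"/"lower"/"equal");
#'   diagonal is NA. Sites with no usable days give NA rows/columns.
#' @export
pairwise_site_matrix <- function(site_days) {
  ids <- names(site_days)
  if (length(ids) < 2) stop("need >= 2 sites")
  k <- length(ids)
  p <- H <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  cls <- dir <- matrix(NA_character_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- site_days[[i]]; b <- site_days[[j]]
    if (!length(a) || !length(b)) next
    kw <- kruskal_wallis(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
    p[i, j] <- p[j, i] <- kw$p
    H[i, j] <- H[j, i] <- kw$statistic
    cls[i, j] <- cls[j, i] <- kw$class
    d <- stats::median(a) - stats::median(b)
    dir[i, j] <- if (d > 0) "higher" else if (d < 0) "lower" else "equal"
    dir[j, i] <- if (d > 0) "lower" else if (d < 0) "higher" else "equal"
  }
  list(p = p, H = H, class = cls, direction = dir)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Ordinary least-squares regression with F-test
#'
#' @param x,y Numeric vectors (n >= 3); `x` must vary.
#' @return List with `slope`, `intercept`, `slope_se`, `r_squared`, `p`
#'   (F-test of the regression) and the underlying `lm` fit.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3")
  if (stats::var(x) == 0) stop("constant x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  f <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       p = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
       fit = fit)
}

#' Metabolic fingerprint of a site
#'
#' Bivariate Gaussian kernel density of the daily (GPP, ER) pairs
#' (Scott's-rule bandwidth), summarising a site's metabolic regime, plus
#' the median point and the fraction of days with positive NEP (net
#' autotrophy; days exactly on the GPP = -ER line count as not autotrophic).
#'
#' @param gpp,er Usable daily rates (>= 5 days).
#' @param n Grid resolution per axis.
#' @param expand Grid margin in bandwidths beyond the data range.
#' @return List with grid vectors `x` (GPP), `y` (ER), density matrix `z`
#'   (integrates to ~1), `median` (named GPP/ER point) and
#'   `autotrophy_fraction`.
#' @export
metabolic_fingerprint <- function(gpp, er, n = 101, expand = 3) {
  if (length(gpp) < 5) stop("need >= 5 usable days")
  stopifnot(length(gpp) == length(er))
  nd <- length(gpp)
  scott <- function(v) stats::sd(v) * nd^(-1 / 6)
  hx <- max(scott(gpp), 1e-3); hy <- max(scott(er), 1e-3)
  lims <- c(range(gpp) + c(-1, 1) * expand * hx,
            range(er) + c(-1, 1) * expand * hy)
  # MASS::kde2d uses normal kernels with sd = h/4
  kd <- MASS::kde2d(gpp, er, h = c(4 * hx, 4 * hy), n = n, lims = lims)
  list(x = kd$x, y = kd$y, z = kd$z,
       median = c(gpp = stats::median(gpp), er = stats::median(er)),
       autotrophy_fraction = mean(gpp + er > 0))
}
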