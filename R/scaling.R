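#' Log-log power-law regression
#'
#' Fits `y = alpha * x^beta` by ordinary least squares of log10(y) on
#' log10(x) (the conventional scaling-law estimator). Returns the
#' intercept on the log10 scale, the exponent with its t-based 95%
#' confidence interval and two-sided p-value against a zero slope, and
#' R^2. Scaling all y by a constant c shifts `log_alpha` by log10(c) and
#' leaves `beta` and `r_squared` unchanged.
#'
#' @param x,y positive numeric vectors of equal length >= 3.
#' @return object of class `power_law_fit`: list with `log_alpha`,
#'   `beta`, `beta_ci95`, `slope_p`, `r_squared`, `n`, and the underlying
#'   `lm` fit.
#' @examples
#' fit <- loglog_power_fit(c(1, 10, 100), c(2, 20, 200))
#' c(fit$beta, fit$log_alpha, fit$r_squared)  # 1, log10(2), 1
#' @export
loglog_power_fit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 points, got ", length(x))
  bad <- which(!(is.finite(x) & x > 0 & is.finite(y) & y > 0))
  if (length(bad))
    stop("x and y must be positive and finite; offending indices: ",
         paste(bad, collapse = ", "))
  df <- data.frame(lx = log10(x), ly = log10(y))
  fit <- stats::lm(ly ~ lx, data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit, "lx", level = 0.95)
  structure(
    list(log_alpha = unname(stats::coef(fit)[1]),
         beta = unname(stats::coef(fit)[2]),
         beta_ci95 = unname(ci[1, ]),
         slope_p = unname(sm$coefficients["lx", "Pr(>|t|)"]),
         r_squared = sm$r.squared,
         n = length(x), fit = fit),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  p <- if (x$slope_p < 5e-4) "< 0.001" else sprintf("= %.3g", x$slope_p)
  cat(sprintf(
    "<power_law_fit> n = %d: log10(y) = %.3f + %.3f log10(x), R^2 = %.3f\n",
    x$n, x$log_alpha, x$beta, x$r_squared))
  cat(sprintf("  exponent 95%% CI (%.3f, %.3f), slope p %s\n",
              x$beta_ci95[1], x$beta_ci95[2], p))
  invisible(x)
}

#' Case-resampling bootstrap of the power-law exponent
#'
#' Resamples (x, y) pairs with replacement `n_boot` times, refits
#' [loglog_power_fit()] on each resample, and summarizes the exponent by
#' its mean, standard deviation and percentile 95% interval. Degenerate
#' resamples (all x identical, slope undefined) are redrawn.
#'
#' @inheritParams loglog_power_fit
#' @param n_boot number of resamples (>= 100).
#' @param seed integer seed.
#' @return list with `mean_beta`, `sd_beta`, `ci95`, `betas`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_exponent <- function(x, y, n_boot = 2000, seed) {
  stopifnot(n_boot >= 100)
  n <- length(x)
  loglog_power_fit(x, y)  # validate inputs up front
  betas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(x[idx])) > 1) break
      }
      lx <- log10(x[idx])
      ly <- log10(y[idx])
      stats::cov(lx, ly) / stats::var(lx)
    }, numeric(1))
  })
  list(mean_beta = mean(betas), sd_beta = stats::sd(betas),
       ci95 = unname(stats::quantile(betas, c(0.025, 0.975))),
       betas = betas, n_boot = n_boot, seed = seed)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: reports the U statistic for the
#' first sample and the p-value, exact (no ties, both groups of size
#' <= `exact_max`) or by normal approximation with tie correction
#' otherwise, as provided by [stats::wilcox.test()].
#'
#' @param a,b non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives refer to the location of `a` relative to `b`).
#' @param exact_max largest per-group size for which the exact p-value is
#'   enumerated; beyond it the normal approximation is used.
#' @return list with `u` (U statistic of `a`), `p`, `method`,
#'   `alternative`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided",
                           exact_max = 12) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !anyDuplicated(c(a, b))
  wt <- stats::wilcox.test(a, b, alternative = alternative,
                           exact = use_exact, correct = !use_exact)
  list(u = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation",
       alternative = alternative)
}
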