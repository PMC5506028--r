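#' Per-interval mortality rate
#'
#' The discrete mortality-rate estimator `m = -(dn/n)(1/dt)` evaluated on a
#' live-count series: for each interval, the per-capita per-day loss relative
#' to the count at the interval start. Intervals starting at zero count are
#' omitted.
#'
#' @param series Either a data frame with a time column (`time_d` or `day`)
#'   and a count column (`n_live_est`, `n_live` or `n`), or a `tissue_run`.
#' @return A data frame of class `mortality_curve`: `time_d` (interval
#'   start), `n_at`, `m` (per day), `delta_t` (days).
#' @export
mortality_rate <- function(series) {
  xy <- extract_series(series)
  if (nrow(xy) < 2) stop("insufficient data: need at least 2 time points",
                         call. = FALSE)
  if (any(diff(xy$time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  t0 <- xy$time[-nrow(xy)]
  n0 <- xy$n[-nrow(xy)]
  n1 <- xy$n[-1]
  dt <- diff(xy$time)
  keep <- n0 > 0
  structure(
    data.frame(time_d = t0[keep], n_at = n0[keep],
               m = -(n1[keep] - n0[keep]) / (n0[keep] * dt[keep]),
               delta_t = dt[keep]),
    class = c("mortality_curve", "data.frame")
  )
}

extract_series <- function(series) {
  if (inherits(series, "tissue_run")) series <- series$trajectory
  stopifnot(is.data.frame(series))
  tcol <- intersect(c("time_d", "day", "time"), names(series))[1]
  ncol_ <- intersect(c("n_live_est", "n_live", "n"), names(series))[1]
  if (is.na(tcol) || is.na(ncol_)) {
    stop("series must have a time and a live-count column", call. = FALSE)
  }
  data.frame(time = series[[tcol]], n = series[[ncol_]])
}

#' Fit the exponential (non-interacting) null model
#'
#' For non-interacting cells the mortality rate is constant and the
#' population decays as `n(t) = n0 * exp(-m t)`. The null is fitted by
#' ordinary least squares of `log n` on `t` over the positive counts.
#'
#' @inheritParams mortality_rate
#' @return List of class `null_fit`: `n0_hat`, `m_hat` (per day),
#'   `r_squared`, `residuals` (per-time log deviations), `times`.
#' @export
fit_null <- function(series) {
  xy <- extract_series(series)
  xy <- xy[xy$n > 0, ]
  if (nrow(xy) < 3) {
    stop("domain error: need at least 3 positive counts", call. = FALSE)
  }
  fit <- stats::lm(log(xy$n) ~ xy$time)
  res <- unname(stats::residuals(fit))
  tss <- sum((log(xy$n) - mean(log(xy$n)))^2)
  structure(
    list(n0_hat = exp(unname(stats::coef(fit)[1])),
         m_hat = -unname(stats::coef(fit)[2]),
         r_squared = if (tss > 0) 1 - sum(res^2) / tss else 1,
         residuals = res,
         times = xy$time),
    class = "null_fit"
  )
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("Exponential null fit: n0 = %.6g, m = %.6g / day, R^2 = %.4f\n",
              x$n0_hat, x$m_hat, x$r_squared))
  invisible(x)
}

#' Classify the mortality-rate vs population trend
#'
#' Regresses the per-interval mortality rate on the normalized live count
#' `n/n0` and classifies the trend by a bootstrap confidence interval of the
#' slope: a CI entirely below zero means mortality rises as the population
#' thins (cooperative cells), entirely above zero means competition, and a CI
#' containing zero is consistent with non-interacting cells.
#'
#' @param curve A `mortality_curve` from [mortality_rate()].
#' @param n0 Initial population used to normalize the abscissa.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param alpha Two-sided CI level (default 0.05).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `trend_result`: `slope` (per day per unit n/n0),
#'   `ci`, `label` in `{"cooperative", "competitive", "non_interacting"}`,
#'   `n0`, `n_boot`.
#' @export
classify_m_vs_n <- function(curve, n0, n_boot = 1000, alpha = 0.05,
                            seed = NULL) {
  stopifnot(is.data.frame(curve), all(c("n_at", "m") %in% names(curve)))
  if (nrow(curve) < 4) {
    stop("insufficient data: need at least 4 (n, m) pairs", call. = FALSE)
  }
  x <- curve$n_at / n0
  y <- curve$m
  if (length(unique(x)) < 2) {
    stop("undefined trend: all population values equal", call. = FALSE)
  }
  slope_of <- function(xs, ys) {
    if (length(unique(xs)) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(ys ~ xs))[2])
  }
  slope <- slope_of(x, y)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      slope_of(x[idx], y[idx])
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  label <- if (ci[2] < 0) "cooperative" else if (ci[1] > 0) "competitive"
           else "non_interacting"
  structure(list(slope = slope, ci = ci, label = label, n0 = n0,
                 n_boot = n_boot),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("m(n) trend: slope %.4g (%.4g, %.4g) -> %s\n",
              x$slope, x$ci[1], x$ci[2], x$label))
  invisible(x)
}

#' Per-interval probability of death
#'
#' `p_t = m_t * dt`, clamped to `[0, 1]`; algebraically identical to
#' `1 - n(t+dt)/n(t)` for positive counts.
#'
#' @inheritParams mortality_rate
#' @return Data frame `time_d`, `p_death`, `delta_t`.
#' @export
probability_of_death <- function(series) {
  mc <- mortality_rate(series)
  data.frame(time_d = mc$time_d,
             p_death = pmin(1, pmax(0, mc$m * mc$delta_t)),
             delta_t = mc$delta_t)
}

#' Rescale a mortality curve to normalized time
#'
#' Maps the time axis to `t/T` (T = tissue lifetime) and linearly
#' interpolates the rate onto a fixed evenly spaced grid on `[0, 1]`, so that
#' failure trajectories of tissues with different lifetimes are comparable.
#'
#' @param curve A `mortality_curve`.
#' @param lifetime A number of days, or the list returned by [lifetime()].
#' @param n_grid Grid size (default 21: 0, 0.05, ..., 1).
#' @return Data frame `t_norm`, `m`.
#' @export
normalize_time <- function(curve, lifetime, n_grid = 21) {
  stopifnot(is.data.frame(curve), all(c("time_d", "m") %in% names(curve)))
  if (is.list(lifetime)) {
    if (isTRUE(lifetime$censored)) {
      stop("censored input: lifetime was not reached", call. = FALSE)
    }
    lifetime <- lifetime$time
  }
  if (!is.numeric(lifetime) || lifetime <= 0) {
    stop("lifetime must be a positive number of days", call. = FALSE)
  }
  grid <- seq(0, 1, length.out = n_grid)
  x <- curve$time_d / lifetime
  y <- curve$m
  if (length(unique(x)) == 1) {
    m_out <- rep(y[1], n_grid)
  } else {
    m_out <- stats::approx(x, y, xout = grid, rule = 2)$y
  }
  data.frame(t_norm = grid, m = m_out)
}

#' Compare two groups with Student's t-test
#'
#' Classical pooled-variance two-sample two-sided t-test, reported with each
#' group's mean and standard deviation, as in the source protocol's
#' statistical analysis (significance at p < 0.05). When both groups have
#' zero variance, p is 1 for equal means and 0 otherwise, by convention.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return List of class `group_comparison`: `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `t`, `df`, `p`, `significant`.
#' @export
compare_groups <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  if (sp2 == 0) {
    tstat <- if (ma == mb) 0 else Inf * sign(ma - mb)
    p <- if (ma == mb) 1 else 0
  } else {
    tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(
    list(mean_a = ma, sd_a = sqrt(va), n_a = na,
         mean_b = mb, sd_b = sqrt(vb), n_b = nb,
         t = tstat, df = df, p = p, significant = p < 0.05),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "A: %.4g +/- %.4g (n=%d)  B: %.4g +/- %.4g (n=%d)  t=%.4g, p=%.4g%s\n",
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b, x$t, x$p,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}
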