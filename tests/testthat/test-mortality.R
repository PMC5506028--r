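test_that("mortality rate reproduces closed forms on exact series", {
  s <- data.frame(time_d = 0:2, n_live_est = c(100, 100, 100))
  expect_equal(mortality_rate(s)$m, c(0, 0))
  # exponential decay sampled at dt=1: every m equals 1 - exp(-0.3)
  tt <- 0:8
  s2 <- data.frame(time_d = tt, n_live_est = 1000 * exp(-0.3 * tt))
  expect_equal(mortality_rate(s2)$m, rep(1 - exp(-0.3), 8))
  # halving population: m = 0.5 per interval
  s3 <- data.frame(time_d = 0:2, n_live_est = c(100, 50, 25))
  expect_equal(mortality_rate(s3)$m, c(0.5, 0.5))
  # intervals starting at zero count are omitted
  s4 <- data.frame(time_d = 0:3, n_live_est = c(100, 0, 0, 0))
  expect_equal(nrow(mortality_rate(s4)), 1)
  expect_error(mortality_rate(data.frame(time_d = 1, n_live_est = 5)),
               "insufficient data")
  expect_error(mortality_rate(data.frame(time_d = c(0, 0), n_live_est = c(5, 4))),
               "strictly increasing")
})

test_that("exponential null fit recovers exact inputs to machine precision", {
  tt <- 0:10
  s <- data.frame(time_d = tt, n_live_est = 5000 * exp(-0.17 * tt))
  fit <- fit_null(s)
  expect_equal(fit$n0_hat, 5000, tolerance = 1e-10)
  expect_equal(fit$m_hat, 0.17, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_error(fit_null(data.frame(time_d = 0:2, n_live_est = c(0, 0, 0))),
               "domain error")
})

test_that("accelerating decay leaves systematically negative late residuals", {
  s <- data.frame(time_d = 0:3, n_live_est = c(1000, 900, 700, 300))
  fit <- fit_null(s)
  expect_lt(tail(fit$residuals, 1), 0)
  expect_gt(fit$residuals[2], 0)  # log-curvature: middle above the line
})

test_that("null fit recovers the binomial-thinning rate from simulations", {
  m_hats <- vapply(1:40, function(i) {
    p <- model_params(1e4, d = 0.2, beta = 0, theta = 0, lambda_int = 0,
                      t_max = 12, seed = 8200 + i)
    fit_null(simulate_tissue(p)$trajectory)$m_hat
  }, numeric(1))
  se <- sd(m_hats) / sqrt(40)
  expect_lt(abs(mean(m_hats) - (-log(0.8))), 3 * se)
})

test_that("m(n) trend classification labels the three regimes", {
  # constant m over varying n -> non-interacting
  flat <- data.frame(n_at = c(1000, 800, 600, 400, 200), m = rep(0.2, 5))
  expect_equal(classify_m_vs_n(flat, 1000, seed = 1)$label, "non_interacting")
  # m decreasing in n -> cooperative
  coop <- data.frame(n_at = c(1000, 500, 250, 125), m = c(0.05, 0.1, 0.2, 0.4))
  expect_equal(classify_m_vs_n(coop, 1000, seed = 1)$label, "cooperative")
  # m increasing in n -> competitive
  comp <- data.frame(n_at = c(1000, 500, 250, 125), m = c(0.4, 0.2, 0.1, 0.05))
  expect_equal(classify_m_vs_n(comp, 1000, seed = 1)$label, "competitive")
  expect_error(classify_m_vs_n(flat[1:3, ], 1000), "at least 4")
  degen <- data.frame(n_at = rep(500, 4), m = 1:4)
  expect_error(classify_m_vs_n(degen, 1000), "undefined trend")
})

test_that("bootstrap CI is seed-reproducible and brackets the jackknife slopes", {
  toy <- data.frame(n_at = c(1000, 800, 600, 400, 200),
                    m = c(0.10, 0.15, 0.25, 0.40, 0.60))
  a <- classify_m_vs_n(toy, 1000, seed = 9)
  b <- classify_m_vs_n(toy, 1000, seed = 9)
  expect_identical(a$ci, b$ci)
  # oracle: exhaustive leave-one-out slopes on the toy input
  x <- toy$n_at / 1000
  jack <- vapply(1:5, function(i) {
    unname(coef(lm(toy$m[-i] ~ x[-i]))[2])
  }, numeric(1))
  expect_lte(a$ci[1], min(jack))
  expect_gte(a$ci[2], max(jack))
})

test_that("probability of death equals one minus the survival ratio", {
  s <- data.frame(time_d = 0:2, n_live_est = c(100, 50, 25))
  expect_equal(probability_of_death(s)$p_death, c(0.5, 0.5))
  # identity check on an arbitrary positive series
  set.seed(3)
  n <- c(1000, sort(round(runif(6, 10, 900)), decreasing = TRUE))
  s2 <- data.frame(time_d = 0:6, n_live_est = n)
  pd <- probability_of_death(s2)
  expect_equal(pd$p_death, 1 - n[-1] / n[-7])
  # constant-rate series gives a flat curve
  tt <- 0:5
  s3 <- data.frame(time_d = tt, n_live_est = 1000 * exp(-0.2 * tt))
  expect_equal(diff(range(probability_of_death(s3)$p_death)), 0)
})

test_that("normalized time maps onto the fixed 21-point grid exactly at nodes", {
  mc <- data.frame(time_d = 0:10, m = seq(0.1, 0.6, length.out = 11))
  nt <- normalize_time(mc, 10)
  expect_equal(nt$t_norm, seq(0, 1, by = 0.05))
  # grid points coinciding with data reproduce the data values
  # (every other grid node falls on a data time)
  expect_equal(nt$m[seq(1, 21, by = 2)], mc$m)
  # constant curves stay constant
  mc2 <- data.frame(time_d = 0:10, m = rep(0.3, 11))
  expect_equal(unique(normalize_time(mc2, 10)$m), 0.3)
  expect_error(normalize_time(mc, list(time = 10, censored = TRUE)),
               "censored")
})

test_that("group comparison matches the hand-computed pooled t-test", {
  cmp <- compare_groups(c(1, 2, 3), c(2, 4, 6))
  # pooled: sp^2 = (2*1 + 2*4)/4 = 2.5; t = -2 / sqrt(2.5 * 2/3)
  expect_equal(cmp$t, -2 / sqrt(2.5 * 2 / 3))
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 2 * pt(-abs(cmp$t), 4))
  # identical groups: p = 1 by the zero-variance convention
  expect_equal(compare_groups(c(1, 1, 1), c(1, 1, 1))$p, 1)
  # clearly separated groups with tiny jitter are significant
  expect_true(compare_groups(c(1, 1.001, 0.999), c(2, 2.001, 1.999))$significant)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
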