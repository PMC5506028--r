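make_state <- function(positions, c = 1, p = 1, G = 0) {
  n <- nrow(positions)
  comp <- data.frame(age_class = "young", senescent = FALSE,
                     c = rep(c, length.out = n), p = rep(p, length.out = n))
  st <- tissue_state(positions, comp)
  st$G <- G
  st
}

test_that("support combines neighborhood fraction and medium, gated by reception", {
  # isolated cell, G = 0 -> s = 0
  st <- make_state(matrix(c(0, 0, 0), 1))
  gr <- build_interaction_graph(st$positions, 10)
  p <- model_params(1, w_global = 1)
  expect_equal(support_levels(st, gr, p), 0)

  # star: center with 4 neighbors, 3 functional; w*G = 0.5 -> s = 1.25
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(-10, 0, 0), c(0, 10, 0), c(0, -10, 0))
  st <- make_state(pos, G = 0.5)
  st$alive[2] <- FALSE
  gr <- build_interaction_graph(pos, 12)
  p <- model_params(5, w_global = 1)
  expect_equal(support_levels(st, gr, p)[1], 1 * (3 / 4 + 0.5))

  # reception knockout: c = 0 -> s = 0 whatever the neighborhood or medium
  st0 <- make_state(pos, c = 0, G = 7)
  expect_equal(support_levels(st0, gr, p), rep(0, 5))
})

test_that("a step with no dynamics only advances day and medium", {
  pos <- place_cells(50, seed = 3)
  st <- make_state(pos)
  gr <- build_interaction_graph(pos, 30)
  p <- model_params(50, d = 0, r = 0, theta = 0, delta = 0.1, n_ref = 50)
  set.seed(1)
  st2 <- step_day(st, gr, p)
  expect_equal(st2$alive, st$alive)
  expect_equal(st2$day, 1)
  expect_equal(st2$G, 0 * 0.9 + 50 / 50)  # full production, no prior medium
  # production scales with the reference-number normalization
  p2 <- model_params(50, d = 0, r = 0, theta = 0, delta = 0.1, n_ref = 500)
  set.seed(1)
  expect_equal(step_day(st, gr, p2)$G, 50 / 500)
})

test_that("threshold cascade propagates to the enumerated fixed point", {
  # 3 mutually adjacent cells; kill one intrinsically (per-cell d); the two
  # survivors then have functional-neighbor fraction 1/2 < 0.6 and die too
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8, 0))
  st <- make_state(pos)
  gr <- build_interaction_graph(pos, 15)
  expect_equal(nrow(gr$edges), 3)
  p <- model_params(3, d = c(1, 0, 0), theta = 0.6, beta = 0)
  set.seed(42)
  st2 <- step_day(st, gr, p)
  expect_equal(sum(st2$alive), 0)
  # with theta = 0 the cascade is disabled: only the intrinsic death occurs
  p0 <- model_params(3, d = c(1, 0, 0), theta = 0, beta = 0)
  set.seed(42)
  st3 <- step_day(st, gr, p0)
  expect_equal(st3$alive, c(FALSE, TRUE, TRUE))
})

test_that("intrinsic failure matches the binomial expectation", {
  n <- 1e4
  pos <- place_cells(n, seed = 9)
  st <- make_state(pos)
  gr <- build_interaction_graph(pos, 0)     # no interactions
  p <- model_params(n, d = 0.1, beta = 0, theta = 0, lambda_int = 0)
  set.seed(100)
  deaths <- vapply(1:100, function(i) {
    n - sum(step_day(st, gr, p)$alive)
  }, numeric(1))
  se <- sqrt(n * 0.1 * 0.9) / sqrt(100)
  expect_lt(abs(mean(deaths) - 1000), 3 * se)
})

test_that("cascade fixed point holds after every step (direct scan)", {
  p <- small_dense_params(n = 1500, seed = 21, theta = 0.3, d = 0.3, beta = 1)
  pos <- place_cells(p$n_cells, p$geometry, seed = 22)
  gr <- build_interaction_graph(pos, p$lambda_int)
  st <- make_state(pos)
  set.seed(23)
  for (k in 1:6) {
    st <- step_day(st, gr, p)
    f <- as.numeric(gr$adjacency %*% as.numeric(st$alive)) / pmax(gr$degree, 1)
    viol <- st$alive & gr$degree >= 1 & f < p$theta
    expect_equal(sum(viol), 0)
    if (!any(st$alive)) break
  }
})

test_that("non-interacting survival follows the closed form", {
  # beta=0, theta=0, r=0, d=0.2: n(5)/n(0) concentrates at 0.8^5
  ratios <- vapply(1:50, function(i) {
    p <- model_params(1e4, d = 0.2, beta = 0, theta = 0, lambda_int = 0,
                      t_max = 5, seed = 3000 + i)
    run <- simulate_tissue(p)
    expect_true(run$censored)  # 33% alive at day 5 > 2%
    tr <- run$trajectory
    tr$n_live[tr$day == 5] / tr$n_live[1]
  }, numeric(1))
  se <- sd(ratios) / sqrt(50)
  expect_lt(abs(mean(ratios) - 0.8^5), 3 * se)
})

test_that("an undamaged tissue is right-censored with constant population", {
  p <- model_params(500, d = 0, theta = 0, t_max = 4, seed = 5)
  run <- simulate_tissue(p)
  expect_true(run$censored)
  expect_equal(unique(run$trajectory$n_live), 500)
  expect_equal(max(run$trajectory$day), 4)
})

test_that("dense interacting tissues outlive their 100x-sparser counterparts", {
  end_day <- function(n, seed) {
    p <- model_params(n, geometry = small_geometry(), lambda_int = 50,
                      seed = seed)
    max(simulate_tissue(p)$trajectory$day)
  }
  # mean degree > 5 in the dense arm
  gr <- build_interaction_graph(place_cells(2000, small_geometry(), seed = 1), 50)
  expect_gt(mean(gr$degree), 5)
  dense <- vapply(1:20, function(i) end_day(2000, 6000 + i), numeric(1))
  sparse <- vapply(1:20, function(i) end_day(20, 6000 + i), numeric(1))
  expect_gt(mean(dense), mean(sparse))
})

test_that("trajectories are deterministic and conserve cell counts", {
  p <- small_dense_params(n = 800, seed = 31, r = 0.1, theta = 0)
  r1 <- simulate_tissue(p)
  r2 <- simulate_tissue(p)
  expect_identical(r1$trajectory, r2$trajectory)
  tr <- r1$trajectory
  expect_equal(tr$n_live,
               tr$n_live[1] - cumsum(tr$new_deaths) + cumsum(tr$new_repairs))
  # with r = 0 the population is non-increasing and deaths balance exactly
  p0 <- small_dense_params(n = 800, seed = 31, r = 0)
  tr0 <- simulate_tissue(p0)$trajectory
  expect_true(all(diff(tr0$n_live) <= 0))
  expect_equal(sum(tr0$new_deaths), tr0$n_live[1] - tr0$n_live[nrow(tr0)])
  expect_equal(tr0$n_live[1], 800)
})

test_that("lifetime responds monotonically to theta and beta under paired seeds", {
  end_day <- function(seed, theta = 0.05, beta = 2) {
    p <- model_params(600, geometry = construct_geometry(0.02, 100),
                      theta = theta, beta = beta, seed = seed)
    max(simulate_tissue(p)$trajectory$day)
  }
  seeds <- 8100 + 1:12
  lo_theta <- vapply(seeds, end_day, numeric(1), theta = 0.05)
  hi_theta <- vapply(seeds, end_day, numeric(1), theta = 0.5)
  expect_true(all(hi_theta <= lo_theta))
  lo_beta <- vapply(seeds, end_day, numeric(1), beta = 0.5)
  hi_beta <- vapply(seeds, end_day, numeric(1), beta = 2.5)
  expect_true(all(hi_beta >= lo_beta))
})

test_that("medium transfer copies G and is inert for reception-blind recipients", {
  pos <- place_cells(20, seed = 2)
  donor <- make_state(pos, G = 3.2)
  donor$day <- 2
  recipient <- make_state(pos)
  out <- transfer_medium(donor, recipient)
  expect_equal(out$G, 3.2)
  expect_equal(out$alive, recipient$alive)
  expect_warning(transfer_medium(make_state(pos, G = 1), recipient),
                 "conditioned for")

  # c = 0 everywhere: transferred medium cannot change the death process
  comp0 <- data.frame(age_class = "young", senescent = FALSE, c = 0, p = 1)
  comp0 <- comp0[rep(1, 400), ]
  p <- model_params(400, geometry = construct_geometry(0.02, 100),
                    d = 0.3, seed = 55)
  with_cm <- simulate_tissue(p, competences = comp0, media_in = rep(5, 61))
  control <- simulate_tissue(p, competences = comp0, media_in = rep(0, 61))
  expect_identical(with_cm$trajectory$n_live, control$trajectory$n_live)
})
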