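test_that("scenario configs round-trip through YAML", {
  sc <- scenario_config(density = "10K", age_class = "pre_aged",
                        stress = TRUE, hypothesis = "H_production_loss",
                        overrides = list(d = 0.3, theta = 0.1),
                        replicates = 4, seed = 12)
  tmp <- tempfile(fileext = ".yaml")
  write_scenario(sc, tmp)
  back <- read_scenario(tmp)
  expect_equal(back, sc)
  unlink(tmp)
})

test_that("scenario parameters honor density, stress and overrides", {
  p <- scenario_params(scenario_config(density = "1K"), 1)
  expect_equal(p$n_cells, 1000L)
  expect_equal(p$dt, 1 / 12)
  p2 <- scenario_params(scenario_config(density = "100K", stress = TRUE), 1)
  expect_equal(p2$n_cells, 100000L)
  expect_equal(p2$sigma, 2)
  expect_equal(p2$dt, 1)
  p3 <- scenario_params(scenario_config(overrides = list(lambda_int = 50)), 2)
  expect_equal(p3$lambda_int, 50)
  # replicates get distinct derived seeds
  expect_false(scenario_params(scenario_config(), 1)$seed ==
                 scenario_params(scenario_config(), 2)$seed)
})

test_that("competence generation encodes age class, mixture and hypothesis", {
  young <- cell_competences(5000, "young", seed = 1)
  expect_lt(mean(young$senescent), 0.02)   # < 1% senescent nominal
  expect_true(all(young$c[!young$senescent] == 1))
  aged_r <- cell_competences(5000, "pre_aged", "H_reception_loss", seed = 1)
  expect_gt(mean(aged_r$senescent), 0.5)   # > 50% senescent
  expect_true(all(aged_r$c < 1))           # reception deficit
  expect_true(all(aged_r$p == 1))          # production intact
  aged_p <- cell_competences(5000, "pre_aged", "H_production_loss", seed = 1)
  expect_true(all(aged_p$p < 1))
  expect_true(all(aged_p$c == 1))
})

test_that("degenerate single-replicate sweeps run with unavailable t-tests", {
  sw <- run_density_sweep(densities = "1K", replicates = 1, seed = 5)
  expect_equal(nrow(sw$lifetimes), 2)
  expect_true(is.na(sw$tests$t))
  expect_true(is.na(sw$tests$p))
})

test_that("oxidative stress shortens lifetimes in every group (paired seeds)", {
  st <- run_stress_sweep(densities = "1K", replicates = 3, seed = 17)
  expect_true(all(st$comparison$mean_stress < st$comparison$mean_no_stress))
})

test_that("donor media schedules shift, decay-accumulate and terminate", {
  run <- structure(list(
    trajectory = data.frame(day = 0:4, G = c(0, 0.5, 0.8, 0.6, 0.3)),
    params = list(delta = 0.1)), class = "tissue_run")
  sched <- donor_media_schedule(run, t_max = 4, offset = 2)
  # first batch: conditioning-period accumulation with decay
  expect_equal(sched[1], 0.5 * 0.9 + 0.8)
  # later batches: the 24h-conditioned harvest at the shifted day
  expect_equal(sched[2:3], c(0.6, 0.3))
  # donor gone -> no factors
  expect_equal(sched[4:5], c(0, 0))
})

test_that("hypothesis verdicts apply the fixed predicate list", {
  mk <- function(ctrl_aged_dense, cm_aged_dense, ctrl_aged_sparse,
                 cm_aged_sparse, ctrl_young, cm_young_young, cm_young_aged) {
    arms <- list(aged_100K_control = ctrl_aged_dense,
                 aged_100K_young_cm = cm_aged_dense,
                 aged_1K_control = ctrl_aged_sparse,
                 aged_1K_young_cm = cm_aged_sparse,
                 young_1K_control = ctrl_young,
                 young_1K_young_cm = cm_young_young,
                 young_1K_aged_cm = cm_young_aged)
    lt <- do.call(rbind, lapply(names(arms), function(a) {
      data.frame(arm = a, replicate = seq_along(arms[[a]]),
                 lifetime_d = arms[[a]], censored = FALSE)
    }))
    list(lifetimes = lt)
  }
  # constructed to satisfy all four predicates
  good <- mk(c(6, 7, 6, 7), c(6, 7, 7, 6), c(5, 6, 5, 6), c(5, 6, 6, 5),
             c(7, 8, 7, 8), c(14, 15, 14, 16), c(9, 10, 9, 11))
  # aged sparse strongly rescued -> violates predicate 2
  bad <- mk(c(6, 7, 6, 7), c(6, 7, 7, 6), c(5, 6, 5, 6), c(10, 11, 10, 12),
            c(7, 8, 7, 8), c(14, 15, 14, 16), c(9, 10, 9, 11))
  v <- evaluate_hypotheses(list(H_reception_loss = good,
                                H_production_loss = bad))
  expect_true(v$overall[["H_reception_loss"]])
  expect_false(v$overall[["H_production_loss"]])
  viol <- v$predicates$H_production_loss
  expect_equal(viol$predicate[!viol$satisfied],
               "aged_sparse_not_rescued_by_young_cm")
  expect_equal(v$best, "H_reception_loss")
  # incomplete matrix is rejected with the missing arm named
  incomplete <- good
  incomplete$lifetimes <- incomplete$lifetimes[
    incomplete$lifetimes$arm != "young_1K_aged_cm", ]
  expect_error(evaluate_hypotheses(list(h = incomplete)), "missing arm")
})

test_that("trend classification window handles short and censored series", {
  # series never reaching 2%: classified on the full (censored) window
  s <- structure(data.frame(time_d = 0:6, dead_est = c(0, rep(50, 6)),
                            n_live_est = 1000 - 50 * (0:6),
                            live_pct = 100 - 5 * (0:6)),
                 class = c("live_series", "data.frame"))
  tr <- classify_series_trend(s, 1000, seed = 2)
  expect_s3_class(tr, "trend_result")
  # too few usable points -> NULL, not an error
  s2 <- s[1:3, ]
  expect_null(classify_series_trend(s2, 1000, seed = 2))
})
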