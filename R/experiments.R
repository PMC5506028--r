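DENSITY_CELLS <- c("1K" = 1e3, "10K" = 1e4, "100K" = 1e5)

#' Scenario configuration
#'
#' Describes one experimental condition: encapsulation density, age class of
#' the cells, oxidative stress, media regime, the aging hypothesis encoded in
#' the competences, replicate count and seed, plus optional overrides of the
#' model parameters and of the population-mixture settings.
#'
#' @param density `"1K"`, `"10K"` or `"100K"` (1e3 / 1e4 / 1e5 cells per
#'   construct).
#' @param age_class `"young"` or `"pre_aged"`.
#' @param stress Logical; oxidative post-stress throughout the experiment
#'   (multiplies the intrinsic failure probability by `sigma_stress`).
#' @param media Media regime: `"none"` (fresh media daily),
#'   `"receive_young_100K"` or `"receive_aged_100K"` (conditioned media
#'   transferred daily from a 100 K donor).
#' @param hypothesis `"H_reception_loss"` (default) or
#'   `"H_production_loss"`: which competence pre-aging degrades.
#' @param overrides Named list overriding [model_params()] arguments.
#' @param replicates Replicate constructs (default 3, as in the protocol).
#' @param seed Top-level integer seed; replicate seeds are derived at fixed
#'   offsets.
#' @param senescent_frac,severe,partial Population mixture settings passed to
#'   [cell_competences()] (`NULL` senescent_frac = class default).
#' @param sigma_stress Stress multiplier applied when `stress = TRUE`.
#' @param aged_d_factor Factor on the intrinsic failure probability of
#'   pre-aged cells (default 1: pre-aging degrades competence, not the
#'   intrinsic rate).
#' @param stop_frac Simulator stop fraction (see [simulate_tissue()]).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(density = c("100K", "10K", "1K"),
                            age_class = c("young", "pre_aged"),
                            stress = FALSE,
                            media = c("none", "receive_young_100K",
                                      "receive_aged_100K"),
                            hypothesis = c("H_reception_loss",
                                           "H_production_loss"),
                            overrides = list(),
                            replicates = 3,
                            seed = 1,
                            senescent_frac = NULL,
                            severe = 0.02,
                            partial = 0.02,
                            sigma_stress = 2,
                            aged_d_factor = 1,
                            stop_frac = 0.02) {
  density <- match.arg(density)
  age_class <- match.arg(age_class)
  media <- match.arg(media)
  hypothesis <- match.arg(hypothesis)
  stopifnot(is.list(overrides), replicates >= 1)
  structure(
    list(density = density, age_class = age_class, stress = stress,
         media = media, hypothesis = hypothesis, overrides = overrides,
         replicates = as.integer(replicates), seed = as.integer(seed),
         senescent_frac = senescent_frac, severe = severe, partial = partial,
         sigma_stress = sigma_stress, aged_d_factor = aged_d_factor,
         stop_frac = stop_frac),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: %s %s%s, media %s, %s, %d replicates, seed %d\n",
    x$density, x$age_class, if (x$stress) " +stress" else "",
    x$media, x$hypothesis, x$replicates, x$seed
  ))
  invisible(x)
}

#' Model parameters for one scenario replicate
#'
#' @param scenario A [scenario_config()].
#' @param rep_i Replicate index (seeds are derived at fixed offsets from the
#'   scenario seed).
#' @return A [model_params()].
#' @export
scenario_params <- function(scenario, rep_i = 1) {
  stopifnot(inherits(scenario, "scenario_config"))
  args <- list(
    n_cells = DENSITY_CELLS[[scenario$density]],
    dt = if (scenario$density == "1K") 1 / 12 else 1,
    sigma = if (scenario$stress) scenario$sigma_stress else 1,
    seed = derive_seed(scenario$seed, 10 * rep_i)
  )
  args[names(scenario$overrides)] <- scenario$overrides
  p <- do.call(model_params, args)
  if (scenario$age_class == "pre_aged" && scenario$aged_d_factor != 1) {
    p$d <- pmin(1, p$d * scenario$aged_d_factor)
  }
  p
}

# Dense tissues are counted on middle slices; sparse 1 K tissues on maximum
# projections (sparsity lets all planes be counted at once).
scenario_protocol <- function(scenario) {
  imaging_protocol(mode = if (scenario$density == "1K") "max_projection"
                          else "slices")
}

#' Run one scenario through the full pipeline
#'
#' Simulate each replicate, emulate the staining/imaging protocol, estimate
#' the live series with the counting pipeline, and analyze mortality:
#' lifetime call, mortality curve and m(n) trend classification per
#' replicate.
#'
#' @param scenario A [scenario_config()].
#' @param media_in Optional incoming-media schedule (used by the
#'   conditioned-media experiment).
#' @param calibration A [calibration_curve()].
#' @details The m(n) trend of each replicate is classified on the analysis
#'   window of its measured series: times up to the recorded lifetime (the
#'   staining protocol stops once at least 98% of the population is dead) and
#'   intervals starting at no less than 20% of the seeded population, below
#'   which the relative error of the count-based live estimate is too large
#'   for a per-capita rate to be meaningful.
#' @return List of class `scenario_result`: `scenario`, `experiment` (from
#'   [generate_experiment()]), `series` (list of `live_series`), `lifetimes`
#'   (data frame `replicate`, `lifetime_d`, `censored`), `trends` (list of
#'   `trend_result` or NULL when undefined).
#' @export
run_scenario <- function(scenario, media_in = NULL,
                         calibration = calibration_curve()) {
  exp_ <- generate_experiment(scenario, media_in = media_in)
  N0 <- DENSITY_CELLS[[scenario$density]]
  series <- estimate_live_series(exp_$records, exp_$protocol, N0, calibration)
  lifetimes <- data.frame(replicate = integer(0), lifetime_d = numeric(0),
                          censored = logical(0))
  trends <- vector("list", length(series))
  for (i in seq_along(series)) {
    lt <- lifetime(series[[i]])
    lifetimes[i, ] <- list(i, lt$time, lt$censored)
    trends[[i]] <- classify_series_trend(series[[i]], N0,
                                         seed = derive_seed(scenario$seed,
                                                            500 + i))
  }
  structure(
    list(scenario = scenario, experiment = exp_, series = series,
         lifetimes = lifetimes, trends = trends),
    class = "scenario_result"
  )
}

# Analysis window for trend classification of a measured live series:
# truncate at the recorded lifetime and keep intervals starting at
# >= floor_frac of the seeded population (see run_scenario Details).
classify_series_trend <- function(series, N0, seed = NULL, floor_frac = 0.2) {
  lt <- lifetime(series)
  s <- series[series$time_d <= lt$time + 1e-9, ]
  tryCatch({
    mc <- mortality_rate(s)
    mc <- mc[mc$n_at >= floor_frac * N0, , drop = FALSE]
    classify_m_vs_n(mc, n0 = N0, seed = seed)
  }, error = function(e) NULL)
}

#' Density sweep: lifetimes and failure curves by density and age class
#'
#' Runs the full pipeline for every density x age-class combination and
#' reports per-replicate lifetimes, group mean +/- SD, the young vs pre-aged
#' Student's t-test per density, and the per-replicate m(n) trend labels.
#'
#' @param densities,age_classes Conditions to cross.
#' @param replicates Replicates per condition.
#' @param seed Top-level seed.
#' @param stress Logical, oxidative stress for all conditions.
#' @param hypothesis Aging hypothesis for the pre-aged competences.
#' @param overrides Model-parameter overrides applied to all conditions.
#' @return List of class `density_sweep`: `lifetimes`, `summary`, `tests`
#'   (young vs pre-aged per density; NA when either group has < 2 values),
#'   `trend_labels`, `results` (list of `scenario_result`).
#' @export
run_density_sweep <- function(densities = c("1K", "10K", "100K"),
                              age_classes = c("young", "pre_aged"),
                              replicates = 3, seed = 1, stress = FALSE,
                              hypothesis = "H_reception_loss",
                              overrides = list()) {
  results <- list()
  rows <- list()
  labels <- list()
  for (dens in densities) {
    for (age in age_classes) {
      sc <- scenario_config(density = dens, age_class = age, stress = stress,
                            hypothesis = hypothesis, overrides = overrides,
                            replicates = replicates,
                            seed = derive_seed(seed, match(dens, names(DENSITY_CELLS))))
      res <- run_scenario(sc)
      key <- paste(dens, age, sep = "_")
      results[[key]] <- res
      lt <- res$lifetimes
      lt$density <- dens; lt$age_class <- age
      rows[[key]] <- lt
      labels[[key]] <- data.frame(
        density = dens, age_class = age,
        replicate = seq_along(res$trends),
        label = vapply(res$trends,
                       function(t) if (is.null(t)) NA_character_ else t$label,
                       character(1))
      )
    }
  }
  lifetimes <- do.call(rbind, rows)
  rownames(lifetimes) <- NULL
  summary_df <- do.call(rbind, lapply(split(
    lifetimes, lifetimes[c("age_class", "density")], drop = TRUE
  ), function(g) data.frame(
    density = g$density[1], age_class = g$age_class[1],
    mean_lifetime_d = mean(g$lifetime_d), sd_lifetime_d = stats::sd(g$lifetime_d),
    n = nrow(g), n_censored = sum(g$censored)
  )))
  rownames(summary_df) <- NULL
  tests <- NULL
  if (all(c("young", "pre_aged") %in% age_classes)) {
    tests <- do.call(rbind, lapply(densities, function(dens) {
      a <- lifetimes$lifetime_d[lifetimes$density == dens &
                                  lifetimes$age_class == "young"]
      b <- lifetimes$lifetime_d[lifetimes$density == dens &
                                  lifetimes$age_class == "pre_aged"]
      if (length(a) < 2 || length(b) < 2) {
        return(data.frame(density = dens, mean_young = mean(a),
                          mean_pre_aged = mean(b), t = NA_real_, p = NA_real_,
                          significant = NA))
      }
      cmp <- compare_groups(a, b)
      data.frame(density = dens, mean_young = cmp$mean_a,
                 mean_pre_aged = cmp$mean_b, t = cmp$t, p = cmp$p,
                 significant = cmp$significant)
    }))
  }
  structure(
    list(lifetimes = lifetimes, summary = summary_df, tests = tests,
         trend_labels = do.call(rbind, labels), results = results,
         seed = seed),
    class = "density_sweep"
  )
}

#' Repeat the density experiment and vote on its qualitative outcomes
#'
#' Repeats the young vs pre-aged density experiment `n_experiments` times
#' (each with the protocol's n = 3 replicate constructs and a Student's
#' t-test), mirroring how the wet experiments were replicated, and collects
#' per-experiment significance calls plus per-replicate m(n) trend labels for
#' the young tissues. Majority votes over these calls are the robust summary
#' of the interdependence signature.
#'
#' @param n_experiments Number of repeated experiments (default 20).
#' @param densities Densities to test.
#' @param replicates Replicates per experiment and group (default 3).
#' @param seed Top-level seed.
#' @return List with `votes` (data frame `experiment`, `density`,
#'   `young_longer_significant`), `labels` (data frame `density`,
#'   `experiment`, `replicate`, `label` for young tissues) and `lifetimes`.
#' @export
repeat_density_experiments <- function(n_experiments = 20,
                                       densities = c("1K", "100K"),
                                       replicates = 3, seed = 1) {
  votes <- list(); labels <- list(); lifetimes <- list()
  for (e in seq_len(n_experiments)) {
    for (dens in densities) {
      lt <- list()
      for (age in c("young", "pre_aged")) {
        sc <- scenario_config(
          density = dens, age_class = age, replicates = replicates,
          seed = derive_seed(seed, 1000 * e +
                               37 * match(dens, names(DENSITY_CELLS)) +
                               3 * (age == "young"))
        )
        res <- run_scenario(sc)
        lt[[age]] <- res$lifetimes$lifetime_d
        lifetimes[[length(lifetimes) + 1]] <-
          data.frame(experiment = e, density = dens, age_class = age,
                     replicate = res$lifetimes$replicate,
                     lifetime_d = res$lifetimes$lifetime_d)
        if (age == "young") {
          labels[[length(labels) + 1]] <- data.frame(
            density = dens, experiment = e,
            replicate = seq_along(res$trends),
            label = vapply(res$trends, function(t)
              if (is.null(t)) NA_character_ else t$label, character(1))
          )
        }
      }
      cmp <- compare_groups(lt$young, lt$pre_aged)
      votes[[length(votes) + 1]] <- data.frame(
        experiment = e, density = dens,
        young_longer_significant = cmp$significant && cmp$mean_a > cmp$mean_b
      )
    }
  }
  list(votes = do.call(rbind, votes), labels = do.call(rbind, labels),
       lifetimes = do.call(rbind, lifetimes))
}

#' Oxidative-stress sweep
#'
#' Runs each density x age-class condition with and without oxidative stress
#' under paired seeds and tabulates the lifetime comparison.
#'
#' @inheritParams run_density_sweep
#' @return List of class `stress_sweep`: `lifetimes` (with `stress` column),
#'   `comparison` (per condition: unstressed vs stressed means, t, p),
#'   `tests_young_vs_aged` (per density, under stress), `sweeps`.
#' @export
run_stress_sweep <- function(densities = c("1K", "100K"),
                             age_classes = c("young", "pre_aged"),
                             replicates = 3, seed = 1,
                             hypothesis = "H_reception_loss",
                             overrides = list()) {
  no_stress <- run_density_sweep(densities, age_classes, replicates, seed,
                                 stress = FALSE, hypothesis = hypothesis,
                                 overrides = overrides)
  stress <- run_density_sweep(densities, age_classes, replicates, seed,
                              stress = TRUE, hypothesis = hypothesis,
                              overrides = overrides)
  lifetimes <- rbind(
    cbind(no_stress$lifetimes, stress = FALSE),
    cbind(stress$lifetimes, stress = TRUE)
  )
  comparison <- do.call(rbind, lapply(densities, function(dens) {
    do.call(rbind, lapply(age_classes, function(age) {
      a <- no_stress$lifetimes
      a <- a$lifetime_d[a$density == dens & a$age_class == age]
      b <- stress$lifetimes
      b <- b$lifetime_d[b$density == dens & b$age_class == age]
      cmp <- if (length(a) >= 2 && length(b) >= 2) compare_groups(a, b) else NULL
      data.frame(density = dens, age_class = age,
                 mean_no_stress = mean(a), mean_stress = mean(b),
                 t = if (is.null(cmp)) NA_real_ else cmp$t,
                 p = if (is.null(cmp)) NA_real_ else cmp$p)
    }))
  }))
  structure(
    list(lifetimes = lifetimes, comparison = comparison,
         tests_young_vs_aged = stress$tests,
         sweeps = list(no_stress = no_stress, stress = stress)),
    class = "stress_sweep"
  )
}

# G level harvested from a donor at each integer day, shifted by the
# conditioning offset: recipient day k receives the donor medium conditioned
# through donor day k + offset (zero once the donor run has ended). The first
# transferred batch sat in the donor throughout the conditioning period, so
# it carries the decay-weighted accumulation of those days' production; later
# batches are 24 h-conditioned.
donor_media_schedule <- function(donor_run, t_max, offset = 2) {
  traj <- donor_run$trajectory
  delta <- donor_run$params$delta
  at_day <- function(day) {
    i <- which(abs(traj$day - day) < 1e-9)
    if (length(i)) traj$G[i[1]] else 0
  }
  out <- vapply(0:t_max, function(k) at_day(k + offset), numeric(1))
  if (offset >= 1) {
    out[1] <- sum(vapply(seq_len(offset), function(t)
      at_day(t) * (1 - delta)^(offset - t), numeric(1)))
  }
  out
}

#' Conditioned-media transfer experiment
#'
#' Reproduces the media-transfer design: 100 K donor tissues (young and
#' pre-aged) are conditioned for `conditioning_days`, then their daily
#' harvested media is given to recipient tissues whose controls receive fresh
#' (non-conditioned) media at the same cadence. Recipient arms share seeds
#' with their controls, so comparisons are paired.
#'
#' Arms: 100 K pre-aged recipients (control / young CM), and the 1 K matrix
#' (young and pre-aged recipients x control / young CM / aged CM).
#'
#' @param hypothesis Which competence pre-aging degrades.
#' @param replicates Replicates per arm.
#' @param seed Top-level seed.
#' @param conditioning_days Donor conditioning period before the first
#'   transfer (default 2).
#' @param overrides Model-parameter overrides for all arms.
#' @return List of class `media_experiment`: `lifetimes` (data frame `arm`,
#'   `replicate`, `lifetime_d`, `censored`), `arms` (list of
#'   `scenario_result`), `donors`, `hypothesis`.
#' @export
run_media_experiment <- function(hypothesis = c("H_reception_loss",
                                                "H_production_loss"),
                                 replicates = 3, seed = 1,
                                 conditioning_days = 2,
                                 overrides = list()) {
  hypothesis <- match.arg(hypothesis)
  t_max_default <- scenario_params(
    scenario_config(overrides = overrides, hypothesis = hypothesis)
  )$t_max

  donor_for <- function(age, rep_i) {
    sc <- scenario_config(density = "100K", age_class = age,
                          hypothesis = hypothesis, overrides = overrides,
                          replicates = 1,
                          seed = derive_seed(seed, 9000 + 100 * rep_i +
                                               (age == "pre_aged")))
    params <- scenario_params(sc, 1)
    competences <- cell_competences(
      params$n_cells, age, hypothesis, senescent_frac = sc$senescent_frac,
      severe = sc$severe, partial = sc$partial,
      seed = derive_seed(params$seed, 1)
    )
    simulate_tissue(params, competences = competences,
                    media_in = rep(0, ceiling(params$t_max) + 1),
                    stop_frac = sc$stop_frac)
  }
  donors <- list(
    young = lapply(seq_len(replicates), function(r) donor_for("young", r)),
    pre_aged = lapply(seq_len(replicates), function(r) donor_for("pre_aged", r))
  )
  media_of <- function(donor_age, rep_i) {
    donor_media_schedule(donors[[donor_age]][[rep_i]], t_max_default,
                         offset = conditioning_days)
  }

  arm_specs <- list(
    aged_100K_control  = list(density = "100K", age = "pre_aged", cm = NULL),
    aged_100K_young_cm = list(density = "100K", age = "pre_aged", cm = "young"),
    young_1K_control   = list(density = "1K", age = "young", cm = NULL),
    young_1K_young_cm  = list(density = "1K", age = "young", cm = "young"),
    young_1K_aged_cm   = list(density = "1K", age = "young", cm = "pre_aged"),
    aged_1K_control    = list(density = "1K", age = "pre_aged", cm = NULL),
    aged_1K_young_cm   = list(density = "1K", age = "pre_aged", cm = "young"),
    aged_1K_aged_cm    = list(density = "1K", age = "pre_aged", cm = "pre_aged")
  )

  arms <- list()
  rows <- list()
  for (arm in names(arm_specs)) {
    spec <- arm_specs[[arm]]
    # paired seeds: arms of the same recipient (density, age) share seeds
    arm_seed <- derive_seed(seed, 100 * match(spec$density, names(DENSITY_CELLS)) +
                              10 * (spec$age == "pre_aged"))
    sc <- scenario_config(density = spec$density, age_class = spec$age,
                          media = if (is.null(spec$cm)) "none"
                                  else paste0("receive_",
                                              if (spec$cm == "young") "young_100K"
                                              else "aged_100K"),
                          hypothesis = hypothesis, overrides = overrides,
                          replicates = replicates, seed = arm_seed)
    res <- if (is.null(spec$cm)) {
      run_scenario(sc)
    } else {
      # per-replicate donor media; emulate replicate-by-replicate
      reps <- lapply(seq_len(replicates), function(r) {
        sc1 <- sc; sc1$replicates <- 1L
        sc1$seed <- arm_seed
        # replicate r of this arm uses the same derived seed as replicate r
        # of its control: run generate_experiment at rep index r
        exp_ <- generate_experiment_single(sc1, rep_i = r,
                                           media_in = media_of(spec$cm, r))
        exp_
      })
      combine_single_runs(sc, reps)
    }
    arms[[arm]] <- res
    lt <- res$lifetimes
    lt$arm <- arm
    rows[[arm]] <- lt
  }
  lifetimes <- do.call(rbind, rows)
  rownames(lifetimes) <- NULL
  structure(
    list(lifetimes = lifetimes, arms = arms, donors = donors,
         hypothesis = hypothesis, replicates = replicates, seed = seed),
    class = "media_experiment"
  )
}

# Run a single replicate of a scenario (at the replicate-index seed) through
# the pipeline; used by the media experiment to pair CM arms with controls.
generate_experiment_single <- function(scenario, rep_i, media_in = NULL) {
  protocol <- scenario_protocol(scenario)
  params <- scenario_params(scenario, rep_i)
  times <- imaging_schedule(scenario$density, params$t_max)
  if (is.null(media_in)) media_in <- rep(0, ceiling(params$t_max) + 1)
  competences <- cell_competences(
    params$n_cells, scenario$age_class, scenario$hypothesis,
    senescent_frac = scenario$senescent_frac,
    severe = scenario$severe, partial = scenario$partial,
    seed = derive_seed(params$seed, 1)
  )
  run <- simulate_tissue(params, competences = competences, media_in = media_in,
                         record_times = times, record_states = TRUE,
                         stop_frac = scenario$stop_frac)
  fp <- assign_footprints(params$geometry, protocol,
                          seed = derive_seed(params$seed, 2))
  obs_times <- run$record_times
  recs <- with_seed(derive_seed(params$seed, 3), {
    acc <- list()
    for (ti in seq_along(obs_times)[-1]) {
      prev <- run$state; now <- run$state
      prev$alive <- run$alive_at[[ti - 1]]
      now$alive <- run$alive_at[[ti]]
      rec <- image_day(prev, now, fp, protocol)
      rec$time_h <- obs_times[ti] * 24
      acc[[length(acc) + 1]] <- rec
    }
    acc
  })
  records <- do.call(rbind, recs)
  records$replicate <- rep_i
  list(run = run, records = records[, c("replicate", "time_h", "stack",
                                        "slice", "mode", "dead_count")],
       protocol = protocol)
}

combine_single_runs <- function(scenario, reps) {
  records <- do.call(rbind, lapply(reps, `[[`, "records"))
  protocol <- reps[[1]]$protocol
  N0 <- DENSITY_CELLS[[scenario$density]]
  series <- estimate_live_series(records, protocol, N0)
  lifetimes <- data.frame(replicate = integer(0), lifetime_d = numeric(0),
                          censored = logical(0))
  for (i in seq_along(series)) {
    lt <- lifetime(series[[i]])
    lifetimes[i, ] <- list(i, lt$time, lt$censored)
  }
  structure(
    list(scenario = scenario,
         experiment = list(records = records, protocol = protocol,
                           truth = lapply(reps, `[[`, "run")),
         series = series, lifetimes = lifetimes, trends = NULL),
    class = "scenario_result"
  )
}

#' Evaluate the aging hypotheses against the media-transfer pattern
#'
#' Applies the fixed predicate list to paired-seed media-experiment results
#' run under each hypothesis: (1) pre-aged dense tissues are NOT rescued by
#' young conditioned media; (2) pre-aged sparse tissues are NOT rescued;
#' (3) young sparse tissues ARE rescued by young conditioned media; and
#' (4) young sparse tissues ARE rescued by pre-aged conditioned media.
#' "Rescued" means the paired lifetime increase is statistically significant
#' (two-sided paired t-test, alpha) AND at least `rescue_min` in relative
#' terms — a biologically meaningful extension, not a marginal shift.
#'
#' @param results Named list of [run_media_experiment()] outputs, one per
#'   hypothesis setting.
#' @param alpha Significance level (default 0.05).
#' @param rescue_min Minimum relative lifetime extension counted as a rescue
#'   (default 0.10).
#' @return List of class `pattern_verdict`: per hypothesis a data frame of
#'   predicates with observed relative changes and p-values, an `overall`
#'   flag (conjunction), and `best` (names of hypotheses matching all
#'   predicates).
#' @export
evaluate_hypotheses <- function(results, alpha = 0.05, rescue_min = 0.10) {
  stopifnot(is.list(results), length(results) >= 1,
            !is.null(names(results)))
  verdict_for <- function(me) {
    lt <- me$lifetimes
    arm_lt <- function(arm) {
      v <- lt[lt$arm == arm, ]
      if (!nrow(v)) stop(sprintf("missing arm: %s", arm), call. = FALSE)
      v$lifetime_d[order(v$replicate)]
    }
    rescue <- function(control, treated) {
      a <- arm_lt(control); b <- arm_lt(treated)
      stopifnot(length(a) == length(b))
      dif <- b - a
      rel <- mean(b) / mean(a) - 1
      p <- if (length(dif) >= 2 && stats::sd(dif) > 0) {
        stats::t.test(dif)$p.value
      } else if (all(dif == 0)) 1 else 0
      list(rescued = (p < alpha) && mean(dif) > 0 && rel >= rescue_min,
           rel = rel, p = p)
    }
    checks <- list(
      aged_dense_not_rescued_by_young_cm =
        rescue("aged_100K_control", "aged_100K_young_cm"),
      aged_sparse_not_rescued_by_young_cm =
        rescue("aged_1K_control", "aged_1K_young_cm"),
      young_sparse_rescued_by_young_cm =
        rescue("young_1K_control", "young_1K_young_cm"),
      young_sparse_rescued_by_aged_cm =
        rescue("young_1K_control", "young_1K_aged_cm")
    )
    expect_rescue <- c(FALSE, FALSE, TRUE, TRUE)
    satisfied <- mapply(function(chk, want) chk$rescued == want,
                        checks, expect_rescue)
    data.frame(
      predicate = names(checks),
      satisfied = unname(satisfied),
      observed_rescued = vapply(checks, `[[`, logical(1), "rescued"),
      rel_change = vapply(checks, `[[`, numeric(1), "rel"),
      p = vapply(checks, `[[`, numeric(1), "p"),
      row.names = NULL
    )
  }
  per_hyp <- lapply(results, verdict_for)
  overall <- vapply(per_hyp, function(df) all(df$satisfied), logical(1))
  structure(
    list(predicates = per_hyp, overall = overall,
         best = names(overall)[overall]),
    class = "pattern_verdict"
  )
}

#' @export
print.pattern_verdict <- function(x, ...) {
  for (h in names(x$predicates)) {
    cat(sprintf("%s: %s\n", h,
                if (x$overall[[h]]) "matches all predicates"
                else paste("violates:",
                           paste(x$predicates[[h]]$predicate[
                             !x$predicates[[h]]$satisfied], collapse = ", "))))
  }
  invisible(x)
}
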