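#' Write and read scenario configurations as YAML
#'
#' @param scenario A [scenario_config()].
#' @param path File path.
#' @return `read_scenario` returns the `scenario_config`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_config"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scenario_config, x)
}

# Stable md5 hash of a scenario/list, used to stamp output files.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(if (is.list(x)) unclass(x) else x, tmp)
  unname(tools::md5sum(tmp))
}

# CSV writers with an embedded config-hash comment line; readers skip it.
write_csv_stamped <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a population trajectory as CSV
#'
#' Columns: `replicate`, `day`, `n_live`, `new_deaths`, `G`.
#'
#' @param runs A `tissue_run` or list of them (one per replicate).
#' @param path File path.
#' @param hash Optional config hash embedded as a comment line.
#' @export
write_trajectory <- function(runs, path, hash = NULL) {
  if (inherits(runs, "tissue_run")) runs <- list(runs)
  df <- do.call(rbind, lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]$trajectory
    data.frame(replicate = i, day = tr$day, n_live = tr$n_live,
               new_deaths = tr$new_deaths, G = tr$G)
  }))
  write_csv_stamped(df, path, hash)
}

#' Write a tissue-state snapshot as CSV
#'
#' Columns: `cell_id`, `x_um`, `y_um`, `z_um`, `alive`, `age_class`, `c`, `p`.
#'
#' @param state A [tissue_state()].
#' @param path File path.
#' @param hash Optional config hash embedded as a comment line.
#' @export
write_snapshot <- function(state, path, hash = NULL) {
  stopifnot(inherits(state, "tissue_state"))
  df <- data.frame(cell_id = seq_len(state$n_cells),
                   x_um = state$positions[, 1], y_um = state$positions[, 2],
                   z_um = state$positions[, 3], alive = state$alive,
                   age_class = state$age_class, c = state$c, p = state$p)
  write_csv_stamped(df, path, hash)
}

#' Save the artifacts of a pipeline run to a directory
#'
#' Writes the live series, lifetimes, imaging records, ground-truth
#' trajectories and the scenario config for each condition of a sweep (or a
#' single `scenario_result`), each stamped with the config hash. [report()]
#' consumes this layout.
#'
#' @param x A `scenario_result`, `density_sweep`, or `media_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run_outputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "scenario_result")) {
    results <- list(scenario = x)
  } else if (inherits(x, "density_sweep")) {
    results <- x$results
  } else if (inherits(x, "media_experiment")) {
    results <- x$arms
  } else {
    stop("unsupported object", call. = FALSE)
  }
  for (key in names(results)) {
    res <- results[[key]]
    hash <- config_hash(res$scenario)
    sub <- file.path(dir, key)
    dir.create(sub, showWarnings = FALSE)
    series_df <- do.call(rbind, lapply(names(res$series), function(r) {
      cbind(replicate = as.integer(r), res$series[[r]])
    }))
    write_csv_stamped(series_df, file.path(sub, "live_series.csv"), hash)
    write_csv_stamped(res$lifetimes, file.path(sub, "lifetimes.csv"), hash)
    write_records(res$experiment$records, file.path(sub, "records.tsv"))
    write_trajectory(res$experiment$truth, file.path(sub, "trajectory.csv"),
                     hash)
    write_scenario(res$scenario, file.path(sub, "scenario.yaml"))
    # per-replicate exponential-null fits and m(n) trend calls
    fits <- lapply(res$series, function(s) {
      f <- tryCatch(fit_null(s), error = function(e) NULL)
      if (is.null(f)) NULL
      else list(n0_hat = f$n0_hat, m_hat = f$m_hat, r_squared = f$r_squared)
    })
    jsonlite::write_json(list(config_hash = hash, fits = fits),
                         file.path(sub, "fits.json"), auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(res$trends)) {
      trends <- lapply(res$trends, function(t) {
        if (is.null(t)) NULL
        else list(slope = t$slope, ci = t$ci, label = t$label)
      })
      jsonlite::write_json(list(config_hash = hash, trends = trends),
                           file.path(sub, "trends.json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  invisible(dir)
}
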