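#' Summarize a saved run directory: tables, plots and a JSON summary
#'
#' Reads the artifacts written by [save_run_outputs()] (one sub-directory per
#' condition), recomputes lifetime summaries and mortality analyses from the
#' saved live series, writes `summary.json` plus a `figures.pdf` with the
#' live-percentage curves, mortality-rate curves m(t) and m(n),
#' probability-of-death and normalized-time plots, and returns the summary.
#' The JSON is deterministic given the inputs.
#'
#' @param dir Directory written by [save_run_outputs()].
#' @param make_plots Set `FALSE` to skip the PDF.
#' @return The summary list, invisibly.
#' @export
report <- function(dir, make_plots = TRUE) {
  if (!dir.exists(dir)) stop("run directory does not exist", call. = FALSE)
  conds <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  required <- c("live_series.csv", "lifetimes.csv", "scenario.yaml")
  missing <- character(0)
  for (cond in conds) {
    absent <- required[!file.exists(file.path(dir, cond, required))]
    if (length(absent)) {
      missing <- c(missing, paste0(cond, "/", absent))
    }
  }
  if (!length(conds)) missing <- "no condition sub-directories"
  if (length(missing)) {
    stop("missing artifacts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  summary <- list()
  series_all <- list()
  for (cond in conds) {
    sub <- file.path(dir, cond)
    series <- read_csv_stamped(file.path(sub, "live_series.csv"))
    lifetimes <- read_csv_stamped(file.path(sub, "lifetimes.csv"))
    sc <- yaml::read_yaml(file.path(sub, "scenario.yaml"))
    N0 <- DENSITY_CELLS[[sc$density]]
    trends <- list()
    for (r in sort(unique(series$replicate))) {
      ss <- series[series$replicate == r, ]
      tr <- classify_series_trend(ss, N0, seed = derive_seed(sc$seed, 500 + r))
      if (!is.null(tr)) trends[[as.character(r)]] <- tr$label
    }
    summary[[cond]] <- list(
      config_hash = config_hash(sc),
      n_replicates = nrow(lifetimes),
      mean_lifetime_d = mean(lifetimes$lifetime_d),
      sd_lifetime_d = if (nrow(lifetimes) > 1) stats::sd(lifetimes$lifetime_d)
                      else NA,
      n_censored = sum(lifetimes$censored),
      trend_labels = unlist(trends, use.names = FALSE)
    )
    series_all[[cond]] <- list(series = series, N0 = N0,
                               lifetimes = lifetimes)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (make_plots) {
    grDevices::pdf(file.path(dir, "figures.pdf"), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(max(2, length(conds)), "Dark 3")
    # live percentage over time
    plot(NA, xlim = c(0, max(vapply(series_all, function(x)
      max(x$series$time_d), numeric(1)))), ylim = c(0, 100),
      xlab = "time (days)", ylab = "live cells (%)", main = "Live cell %")
    for (i in seq_along(conds)) {
      s <- series_all[[conds[i]]]$series
      for (r in unique(s$replicate)) {
        ss <- s[s$replicate == r, ]
        graphics::lines(ss$time_d, ss$live_pct, col = pal[i])
      }
    }
    graphics::legend("topright", legend = conds, col = pal[seq_along(conds)],
                     lty = 1, cex = 0.7)
    # m(t), m(n), p(death), normalized time
    for (what in c("m_t", "m_n", "p_death", "norm_t")) {
      first <- TRUE
      for (i in seq_along(conds)) {
        x <- series_all[[conds[i]]]
        for (r in unique(x$series$replicate)) {
          ss <- x$series[x$series$replicate == r, ]
          mc <- tryCatch(mortality_rate(ss), error = function(e) NULL)
          if (is.null(mc) || !nrow(mc)) next
          xy <- switch(what,
            m_t = list(x = mc$time_d, y = mc$m, xlab = "time (days)",
                       ylab = "m (1/day)", main = "Mortality rate m(t)"),
            m_n = list(x = mc$n_at / x$N0, y = mc$m, xlab = "n / n0",
                       ylab = "m (1/day)", main = "Mortality rate m(n)"),
            p_death = {
              pd <- probability_of_death(ss)
              list(x = pd$time_d, y = pd$p_death, xlab = "time (days)",
                   ylab = "P(death)", main = "Probability of death")
            },
            norm_t = {
              lt <- lifetime(ss)
              if (lt$censored) next
              nt <- normalize_time(mc, lt)
              list(x = nt$t_norm, y = nt$m, xlab = "t / T",
                   ylab = "m (1/day)", main = "Normalized-time mortality")
            })
          if (first) {
            plot(xy$x, xy$y, type = "l", col = pal[i], xlab = xy$xlab,
                 ylab = xy$ylab, main = xy$main)
            first <- FALSE
          } else {
            graphics::lines(xy$x, xy$y, col = pal[i])
          }
        }
      }
      if (!first) {
        graphics::legend("topright", legend = conds,
                         col = pal[seq_along(conds)], lty = 1, cex = 0.7)
      }
    }
    # lifetime bars
    means <- vapply(summary, `[[`, numeric(1), "mean_lifetime_d")
    sds <- vapply(summary, function(s)
      if (is.na(s$sd_lifetime_d)) 0 else s$sd_lifetime_d, numeric(1))
    bp <- graphics::barplot(means, names.arg = names(means), las = 2,
                            cex.names = 0.6, ylab = "lifetime (days)",
                            main = "Tissue lifetimes",
                            ylim = c(0, max(means + sds) * 1.15))
    graphics::arrows(bp, means - sds, bp, means + sds, angle = 90, code = 3,
                     length = 0.03)
  }
  invisible(summary)
}
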