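#' Affine calibration of raw dead-cell counts
#'
#' Raw image counts are normalized with an affine calibration curve:
#' `actual = (raw - intercept) / gain`, clamped at zero. The identity
#' calibration (gain 1, intercept 0) is the default.
#'
#' @param gain Multiplicative factor (> 0).
#' @param intercept Additive count offset.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(gain = 1, intercept = 0) {
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  structure(list(gain = gain, intercept = intercept),
            class = "calibration_curve")
}

calibrate <- function(raw, calibration) {
  pmax(0, (raw - calibration$intercept) / calibration$gain)
}

#' Dead cells per gel from middle-slice counts
#'
#' The estimator for dense tissues: the per-image counts from the central
#' slices of each stack are averaged, calibrated, and scaled up by the number
#' of slices per stack and by the inverse of the per-stack field-of-view
#' fraction (x8 for the default 1:8 ratio).
#'
#' @param counts Vector of exactly `n_stacks * middle_slices` slice counts
#'   (default 9) for one staining time.
#' @param protocol An [imaging_protocol()].
#' @param calibration A [calibration_curve()].
#' @return Estimated dead cells in the whole gel (non-negative real).
#' @examples
#' p <- imaging_protocol()
#' dead_per_gel_slices(rep(5, 9), p)  # 5 * 10 * 8 = 400
#' @export
dead_per_gel_slices <- function(counts, protocol,
                                calibration = calibration_curve()) {
  stopifnot(inherits(protocol, "imaging_protocol"))
  expected <- protocol$n_stacks * protocol$middle_slices
  if (length(counts) != expected || anyNA(counts)) {
    stop(sprintf("incomplete record: expected %d counts, got %d",
                 expected, length(counts)), call. = FALSE)
  }
  calibrate(mean(counts), calibration) * protocol$n_slices /
    protocol$stack_fov_fraction
}

#' Dead cells per gel from maximum projections
#'
#' The estimator for sparse tissues: one summed count per stack projection,
#' averaged over stacks, calibrated, and scaled by the inverse field-of-view
#' fraction.
#'
#' @param counts Vector of exactly `n_stacks` projection counts.
#' @inheritParams dead_per_gel_slices
#' @return Estimated dead cells in the whole gel.
#' @export
dead_per_gel_projection <- function(counts, protocol,
                                    calibration = calibration_curve()) {
  stopifnot(inherits(protocol, "imaging_protocol"))
  if (length(counts) != protocol$n_stacks || anyNA(counts)) {
    stop(sprintf("incomplete record: expected %d counts, got %d",
                 protocol$n_stacks, length(counts)), call. = FALSE)
  }
  calibrate(mean(counts), calibration) / protocol$stack_fov_fraction
}

#' Live-cell series by cumulative subtraction
#'
#' The live count at time 0 is assumed equal to the theoretical encapsulated
#' number; each staining's estimated dead count is subtracted from the
#' previous live count (clamped at zero), and the live percentage is computed
#' against the theoretical total.
#'
#' @param dead_est Estimated dead cells per staining interval (one value per
#'   imaging time after time 0).
#' @param N0 Theoretical initial cell number (> 0).
#' @param times Imaging times in days, of length `length(dead_est) + 1`
#'   (default `0:length(dead_est)`, i.e. daily imaging).
#' @return A data frame of class `live_series`: `time_d`, `dead_est`,
#'   `n_live_est`, `live_pct`.
#' @examples
#' live_series(c(400, 600), 100000)  # n_live 100000, 99600, 99000
#' @export
live_series <- function(dead_est, N0, times = NULL) {
  if (N0 <= 0) stop("N0 must be > 0", call. = FALSE)
  if (any(dead_est < 0)) stop("dead estimates must be >= 0", call. = FALSE)
  if (is.null(times)) times <- 0:length(dead_est)
  stopifnot(length(times) == length(dead_est) + 1)
  n_live <- numeric(length(times))
  n_live[1] <- N0
  for (i in seq_along(dead_est)) {
    n_live[i + 1] <- max(0, n_live[i] - dead_est[i])
  }
  structure(
    data.frame(time_d = times, dead_est = c(0, dead_est),
               n_live_est = n_live, live_pct = 100 * n_live / N0),
    class = c("live_series", "data.frame")
  )
}

#' Tissue lifetime from a live-percentage series
#'
#' The lifetime is the first recorded time at which at least 98% of the
#' initial population is dead (live percentage at most 2%). If the series
#' never reaches the threshold the result is right-censored at the last
#' observed time.
#'
#' @param series A `live_series` data frame (or any data frame with columns
#'   `time_d` and `live_pct`).
#' @return List with `time` (days) and `censored` (logical).
#' @export
lifetime <- function(series) {
  stopifnot(is.data.frame(series), nrow(series) >= 1,
            all(c("time_d", "live_pct") %in% names(series)))
  hit <- which(series$live_pct <= 2)
  if (length(hit)) {
    list(time = series$time_d[hit[1]], censored = FALSE)
  } else {
    list(time = series$time_d[nrow(series)], censored = TRUE)
  }
}

#' Estimate live-cell series from imaging records
#'
#' Applies the per-gel dead-cell estimator appropriate to each record's mode
#' (middle slices for dense tissues, maximum projections for sparse ones) at
#' every imaging time, then runs the cumulative live-cell bookkeeping.
#'
#' @param records Records data frame (columns `replicate`, `time_h`, `stack`,
#'   `slice`, `mode`, `dead_count`), as produced by [generate_experiment()].
#' @param protocol The [imaging_protocol()] used.
#' @param N0 Theoretical initial cell number.
#' @param calibration A [calibration_curve()].
#' @return A named list of `live_series`, one per replicate.
#' @export
estimate_live_series <- function(records, protocol, N0,
                                 calibration = calibration_curve()) {
  stopifnot(is.data.frame(records))
  out <- list()
  for (rep_i in sort(unique(records$replicate))) {
    rr <- records[records$replicate == rep_i, ]
    times_h <- sort(unique(rr$time_h))
    dead_est <- vapply(times_h, function(th) {
      day_rec <- rr[rr$time_h == th, ]
      if (day_rec$mode[1] == "slices") {
        dead_per_gel_slices(day_rec$dead_count, protocol, calibration)
      } else {
        dead_per_gel_projection(day_rec$dead_count, protocol, calibration)
      }
    }, numeric(1))
    out[[as.character(rep_i)]] <-
      live_series(dead_est, N0, times = c(0, times_h / 24))
  }
  out
}
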