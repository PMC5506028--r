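#' Imaging protocol for dead-cell staining
#'
#' Describes the daily dead-cell imaging of a construct: a few z-stacks are
#' taken at random points of the gel, each stack covering a fixed fraction of
#' the footprint and split into equal optical slices. Dense tissues are
#' counted on the central slices of each stack; sparse tissues on the maximum
#' projection of each stack.
#'
#' @param n_stacks Number of stacks per construct (default 3).
#' @param stack_fov_fraction Fraction of the gel footprint covered by one
#'   stack's field of view (default 1/8).
#' @param n_slices Optical slices per stack (default 10).
#' @param middle_slices Number of central slices counted in `"slices"` mode
#'   (default 3).
#' @param mode `"slices"` (count middle slices separately) or
#'   `"max_projection"` (one summed count per stack).
#' @param detection_gain True-positive detection probability per dead cell,
#'   in (0, 1].
#' @param count_noise `"none"` or `"poisson"` (extra Poisson jitter on each
#'   reported count, mean-preserving).
#' @return An object of class `imaging_protocol`.
#' @export
imaging_protocol <- function(n_stacks = 3, stack_fov_fraction = 1 / 8,
                             n_slices = 10, middle_slices = 3,
                             mode = c("slices", "max_projection"),
                             detection_gain = 1,
                             count_noise = c("none", "poisson")) {
  mode <- match.arg(mode)
  count_noise <- match.arg(count_noise)
  if (n_stacks < 1 || n_stacks != round(n_stacks)) {
    stop("n_stacks must be a positive integer", call. = FALSE)
  }
  if (stack_fov_fraction <= 0 || stack_fov_fraction > 1) {
    stop("stack_fov_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (n_stacks * stack_fov_fraction > 1 + 1e-12) {
    stop("infeasible protocol: n_stacks * stack_fov_fraction exceeds 1",
         call. = FALSE)
  }
  if (n_slices < 1 || middle_slices < 1 || middle_slices > n_slices) {
    stop("middle_slices must lie in [1, n_slices]", call. = FALSE)
  }
  if (detection_gain <= 0 || detection_gain > 1) {
    stop("detection_gain must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_stacks = as.integer(n_stacks),
         stack_fov_fraction = stack_fov_fraction,
         n_slices = as.integer(n_slices),
         middle_slices = as.integer(middle_slices),
         mode = mode, detection_gain = detection_gain,
         count_noise = count_noise),
    class = "imaging_protocol"
  )
}

# Indices of the central slices counted in "slices" mode.
middle_slice_indices <- function(protocol) {
  center <- ceiling(protocol$n_slices / 2)
  center + seq_len(protocol$middle_slices) - ceiling(protocol$middle_slices / 2)
}

# Place n disjoint axis-aligned square footprints, each covering `frac` of the
# footprint area, at seeded random offsets. Shared by the imaging emulator and
# the distance-analysis subsampling.
place_footprints <- function(geometry, n, frac, seed = NULL, max_tries = 2000) {
  side_x <- sqrt(frac) * geometry$lx_um
  side_y <- sqrt(frac) * geometry$ly_um
  if (n * frac > 1 + 1e-12 || side_x > geometry$lx_um + 1e-9) {
    stop("infeasible footprint configuration", call. = FALSE)
  }
  with_seed(seed, {
    # sequential rejection with global restarts: a late footprint can be
    # boxed out by unlucky early placements, so restart the whole layout
    for (attempt in seq_len(max_tries)) {
      placed <- matrix(NA_real_, n, 4,
                       dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
      done <- TRUE
      for (k in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(50)) {
          x0 <- stats::runif(1, 0, geometry$lx_um - side_x)
          y0 <- stats::runif(1, 0, geometry$ly_um - side_y)
          x1 <- x0 + side_x; y1 <- y0 + side_y
          if (k == 1) { ok <- TRUE } else {
            prev <- placed[seq_len(k - 1), , drop = FALSE]
            overlap <- x0 < prev[, "x1"] & x1 > prev[, "x0"] &
              y0 < prev[, "y1"] & y1 > prev[, "y0"]
            ok <- !any(overlap)
          }
          if (ok) { placed[k, ] <- c(x0, y0, x1, y1); break }
        }
        if (!ok) { done <- FALSE; break }
      }
      if (done) return(placed)
    }
    stop("could not place disjoint footprints (configuration error)",
         call. = FALSE)
  })
}

#' Assign stack footprints and slice boundaries for imaging
#'
#' @param geometry A [construct_geometry()].
#' @param protocol An [imaging_protocol()].
#' @param seed Integer seed for the footprint offsets.
#' @return An object of class `stack_footprints`: list with `footprints`
#'   (matrix `x0,y0,x1,y1` in um, one row per stack) and `slice_edges`
#'   (z boundaries partitioning the thickness into `n_slices` equal bins).
#' @export
assign_footprints <- function(geometry, protocol, seed = NULL) {
  stopifnot(inherits(geometry, "construct_geometry"),
            inherits(protocol, "imaging_protocol"))
  fp <- place_footprints(geometry, protocol$n_stacks,
                         protocol$stack_fov_fraction, seed)
  structure(
    list(footprints = fp,
         slice_edges = seq(0, geometry$thickness_um,
                           length.out = protocol$n_slices + 1)),
    class = "stack_footprints"
  )
}

#' Image one staining time point
#'
#' Bins the cells that died since the previous imaging into the stack
#' footprints and z-slices, applies the detection probability and optional
#' count jitter, and returns the per-slice (or per-projection) dead-cell
#' counts — the raw observable of the protocol.
#'
#' @param prev_state,state [tissue_state()] objects sharing cell identities;
#'   `prev_state` is the previous imaging time.
#' @param footprints An [assign_footprints()] result.
#' @param protocol An [imaging_protocol()].
#' @return Data frame with columns `stack`, `slice` (`NA` for projections),
#'   `mode`, `dead_count`.
#' @export
image_day <- function(prev_state, state, footprints, protocol) {
  stopifnot(inherits(protocol, "imaging_protocol"),
            inherits(footprints, "stack_footprints"))
  if (!identical(dim(prev_state$positions), dim(state$positions)) ||
      !isTRUE(all.equal(prev_state$positions, state$positions))) {
    stop("inconsistent states: cell identities differ", call. = FALSE)
  }
  new_dead <- prev_state$alive & !state$alive
  pos <- state$positions
  edges <- footprints$slice_edges
  mid <- middle_slice_indices(protocol)
  out <- list()
  for (k in seq_len(protocol$n_stacks)) {
    fp <- footprints$footprints[k, ]
    sel <- new_dead &
      pos[, 1] >= fp["x0"] & pos[, 1] <= fp["x1"] &
      pos[, 2] >= fp["y0"] & pos[, 2] <= fp["y1"]
    zbin <- findInterval(pos[sel, 3], edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
    if (protocol$mode == "slices") {
      counts <- tabulate(zbin, nbins = protocol$n_slices)[mid]
      out[[k]] <- data.frame(stack = k, slice = mid, mode = "slices",
                             dead_count = counts)
    } else {
      out[[k]] <- data.frame(stack = k, slice = NA_integer_,
                             mode = "max_projection",
                             dead_count = length(zbin))
    }
  }
  rec <- do.call(rbind, out)
  if (protocol$detection_gain < 1) {
    rec$dead_count <- stats::rbinom(nrow(rec), rec$dead_count,
                                    protocol$detection_gain)
  }
  if (protocol$count_noise == "poisson") {
    rec$dead_count <- stats::rpois(nrow(rec), rec$dead_count)
  }
  rec
}

#' Imaging schedule for a given density
#'
#' Dense (10 K, 100 K) tissues are stained daily; 1 K tissues additionally at
#' 2, 4, 6 and 20 hours on the first day.
#'
#' @param density `"1K"`, `"10K"` or `"100K"`.
#' @param t_max Last imaging day.
#' @return Numeric vector of imaging times in days (starting at 0).
#' @export
imaging_schedule <- function(density, t_max) {
  daily <- 0:ceiling(t_max)
  if (density == "1K") {
    sort(unique(c(c(0, 2, 4, 6, 20, 24) / 24, daily[daily >= 1])))
  } else {
    daily
  }
}

#' Generate a full synthetic imaging experiment
#'
#' Runs the failure simulator for each replicate of a scenario, images the
#' construct on the protocol schedule and returns both the observable imaging
#' records and the hidden ground truth (for oracle tests).
#'
#' @param scenario A [scenario_config()].
#' @param n_replicates Number of replicate constructs (default from the
#'   scenario, itself defaulting to 3 as in the wet protocol).
#' @param media_in Optional incoming-media schedule (see [simulate_tissue()]);
#'   default fresh media daily.
#' @return List with `records` (data frame `replicate`, `time_h`, `stack`,
#'   `slice`, `mode`, `dead_count`), `truth` (list of `tissue_run`),
#'   `protocol`, `footprints` (per replicate), `times_d`, and `scenario`.
#' @export
generate_experiment <- function(scenario, n_replicates = NULL, media_in = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(n_replicates)) n_replicates <- scenario$replicates
  protocol <- scenario_protocol(scenario)
  records <- list()
  truth <- vector("list", n_replicates)
  fps <- vector("list", n_replicates)
  times <- imaging_schedule(scenario$density, scenario_params(scenario, 1)$t_max)
  for (rep_i in seq_len(n_replicates)) {
    params <- scenario_params(scenario, rep_i)
    mi <- media_in
    if (is.null(mi)) mi <- rep(0, ceiling(params$t_max) + 1)
    competences <- cell_competences(
      params$n_cells, scenario$age_class, scenario$hypothesis,
      senescent_frac = scenario$senescent_frac,
      severe = scenario$severe, partial = scenario$partial,
      seed = derive_seed(params$seed, 1)
    )
    run <- simulate_tissue(params, competences = competences, media_in = mi,
                           record_times = times, record_states = TRUE,
                           stop_frac = scenario$stop_frac)
    fp <- assign_footprints(params$geometry, protocol,
                            seed = derive_seed(params$seed, 2))
    obs_times <- run$record_times
    reps <- list()
    noise_seed <- derive_seed(params$seed, 3)
    reps <- with_seed(noise_seed, {
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
    if (length(reps)) {
      rr <- do.call(rbind, reps)
      rr$replicate <- rep_i
      records[[rep_i]] <- rr[, c("replicate", "time_h", "stack", "slice",
                                 "mode", "dead_count")]
    }
    truth[[rep_i]] <- run
    fps[[rep_i]] <- fp
  }
  list(records = do.call(rbind, records), truth = truth, protocol = protocol,
       footprints = fps, times_d = times, scenario = scenario)
}

#' Write / read imaging records as TSV
#'
#' @param records Records data frame from [generate_experiment()].
#' @param path File path.
#' @return `read_records` returns the records data frame.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
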