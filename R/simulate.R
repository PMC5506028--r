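#' Cell competence profiles for young and pre-aged populations
#'
#' Generates per-cell reception (`c`) and production (`p`) competences.
#' Pre-aged populations are a mixture: a senescent fraction carries a severe
#' deficit and the remaining pre-aged cells a partial one, emulating
#' populations in which most cells stain positive for senescence markers while
#' essentially all cells show elevated DNA damage. Which competence is
#' degraded depends on the aging hypothesis: under reception loss the aged
#' cells cannot receive/process cooperative factors (low `c`, normal `p`);
#' under production loss they cannot produce them (low `p`, normal `c`).
#'
#' @param n Number of cells.
#' @param age_class `"young"` or `"pre_aged"`.
#' @param hypothesis `"H_reception_loss"` (default) or `"H_production_loss"`.
#' @param senescent_frac Fraction of severely affected cells; defaults to 0.7
#'   for pre-aged and 0.005 for young populations.
#' @param severe Competence of severely affected (senescent) cells
#'   (default 0.02).
#' @param partial Competence of the remaining pre-aged cells (default 0.02).
#' @param seed Integer seed for the senescence assignment.
#' @return A data frame with columns `age_class`, `senescent`, `c`, `p`.
#' @export
cell_competences <- function(n,
                             age_class = c("young", "pre_aged"),
                             hypothesis = c("H_reception_loss", "H_production_loss"),
                             senescent_frac = NULL,
                             severe = 0.02,
                             partial = 0.02,
                             seed = NULL) {
  age_class <- match.arg(age_class)
  hypothesis <- match.arg(hypothesis)
  if (is.null(senescent_frac)) {
    senescent_frac <- if (age_class == "pre_aged") 0.7 else 0.005
  }
  senescent <- with_seed(seed, stats::runif(n) < senescent_frac)
  cc <- rep(1, n)
  pp <- rep(1, n)
  deficit <- ifelse(senescent, severe,
                    if (age_class == "pre_aged") partial else 1)
  if (hypothesis == "H_reception_loss") cc <- deficit else pp <- deficit
  data.frame(age_class = rep(age_class, n), senescent = senescent,
             c = cc, p = pp)
}

#' Create a tissue state
#'
#' @param positions `n x 3` matrix of cell positions (um).
#' @param competences Data frame from [cell_competences()] (or with columns
#'   `age_class`, `c`, `p`); `NULL` gives a fully competent young population.
#' @param G Initial shared-medium cooperative-factor level (>= 0).
#' @param day Days elapsed (>= 0).
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(positions, competences = NULL, G = 0, day = 0) {
  if (is.data.frame(positions)) positions <- as.matrix(positions)
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  n <- nrow(positions)
  if (is.null(competences)) {
    competences <- cell_competences(n, "young", senescent_frac = 0)
  }
  stopifnot(nrow(competences) == n,
            all(c("age_class", "c", "p") %in% names(competences)))
  if (any(competences$c < 0 | competences$c > 1) ||
      any(competences$p < 0 | competences$p > 1)) {
    stop("competences c and p must lie in [0, 1]", call. = FALSE)
  }
  if (G < 0) stop("G must be >= 0", call. = FALSE)
  if (day < 0) stop("day must be >= 0", call. = FALSE)
  structure(
    list(positions = positions, alive = rep(TRUE, n),
         age_class = as.character(competences$age_class),
         c = competences$c, p = competences$p,
         G = G, day = day, n_cells = n),
    class = "tissue_state"
  )
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("Tissue state: %d cells (%d alive, %.1f%%), day %.3g, G = %.4g\n",
              x$n_cells, sum(x$alive), 100 * mean(x$alive), x$day, x$G))
  invisible(x)
}

#' Cooperative support received by each cell
#'
#' Support combines the fraction of functional graph neighbors with the
#' shared-medium factor level, both gated by the cell's reception competence:
#' `s_i = c_i * (f_i + w_global * G)` where `f_i` is the functional fraction
#' of cell i's neighbors (0 for isolated cells).
#'
#' @param state A [tissue_state()].
#' @param graph An [build_interaction_graph()] result for `state$positions`.
#' @param params A [model_params()].
#' @return Numeric vector of support levels, one per cell.
#' @export
support_levels <- function(state, graph, params) {
  stopifnot(inherits(state, "tissue_state"), inherits(graph, "interaction_graph"))
  if (graph$n != state$n_cells) {
    stop("graph and state have different cell counts", call. = FALSE)
  }
  f <- functional_neighbor_fraction(state$alive, graph)
  state$c * (f + params$w_global * state$G)
}

functional_neighbor_fraction <- function(alive, graph) {
  if (graph$n == 0) return(numeric(0))
  nf <- as.numeric(graph$adjacency %*% as.numeric(alive))
  f <- nf / pmax(graph$degree, 1)
  f[graph$degree == 0] <- 0
  f
}

#' Advance a tissue state by one time step
#'
#' One step applies, in order: (1) intrinsic failure, each functional cell
#' dying with probability `1 - (1 - d*sigma)^(exp(-beta*s_i) * dt)`;
#' (2) a synchronous cascade sweep repeated to its fixed point, in which every
#' functional cell with at least one neighbor and functional-neighbor fraction
#' below `theta` fails; (3) repair, each failed cell reviving with probability
#' `r*dt`; and (4) the shared-medium update
#' `G <- G*(1-delta)^dt + dt * sum(p_i over functional cells) / n_ref`
#' (see [model_params()] for the reference-number normalization).
#'
#' @inheritParams support_levels
#' @return The updated `tissue_state` (day incremented by `dt`).
#' @export
step_day <- function(state, graph, params) {
  stopifnot(inherits(state, "tissue_state"))
  n <- state$n_cells
  dt <- params$dt
  s <- support_levels(state, graph, params)
  # (1) intrinsic failure
  q <- 1 - (1 - params$d * params$sigma)^(exp(-params$beta * s) * dt)
  u <- stats::runif(n)
  state$alive <- state$alive & !(u < q)
  # (2) threshold cascade, synchronous sweeps to fixed point
  if (params$theta > 0 && any(state$alive)) {
    repeat {
      f <- functional_neighbor_fraction(state$alive, graph)
      doomed <- state$alive & graph$degree >= 1 & f < params$theta
      if (!any(doomed)) break
      state$alive[doomed] <- FALSE
    }
  }
  # (3) repair
  if (params$r > 0) {
    failed <- !state$alive
    revived <- failed & (stats::runif(n) < params$r * dt)
    state$alive[revived] <- TRUE
  }
  # (4) shared-medium update
  state$G <- state$G * (1 - params$delta)^dt +
    dt * sum(state$p[state$alive]) / params$n_ref
  state$day <- state$day + dt
  state
}

#' Transfer conditioned medium from a donor to a recipient tissue
#'
#' Sets the recipient's shared-medium factor level to the donor's; all other
#' recipient fields are unchanged. Donors should have been conditioned for at
#' least `min_days` before their medium is harvested.
#'
#' @param donor,recipient [tissue_state()] objects.
#' @param min_days Minimum donor conditioning period in days (default 2).
#' @return The recipient state with `G` replaced by the donor's.
#' @export
transfer_medium <- function(donor, recipient, min_days = 2) {
  stopifnot(inherits(donor, "tissue_state"), inherits(recipient, "tissue_state"))
  if (donor$day < min_days) {
    warning(sprintf("donor conditioned for %.3g days (< %g)", donor$day, min_days))
  }
  recipient$G <- donor$G
  recipient
}

#' Simulate a tissue construct to death or censoring
#'
#' Places cells, builds the interaction graph and iterates [step_day()] from
#' day 0 until the live fraction falls to at most 2% of the initial population
#' or `t_max` is reached (the run is then flagged right-censored).
#'
#' By default the medium is a closed system evolving per [step_day()]. A
#' `media_in` vector emulates daily media changes: entry k is the factor level
#' G of the incoming medium applied at the start of day k-1 (all zeros = fresh
#' non-conditioned media every day; a donor's harvested levels = conditioned
#' media).
#'
#' @param params A [model_params()]; `params$seed` makes the run reproducible.
#' @param competences Optional data frame from [cell_competences()].
#' @param media_in Optional numeric vector of incoming medium factor levels
#'   applied at each daily boundary (see Details), or `NULL` for a closed
#'   system.
#' @param record_times Days at which to record the trajectory (and states);
#'   default every step.
#' @param record_states If `TRUE`, keep the alive vector at each recorded
#'   time (needed by the imaging emulator).
#' @param positions,graph Optional pre-computed placement and graph.
#' @param stop_frac Live fraction at or below which the run stops (default
#'   0.02, the 98%-dead lifetime rule; scenario pipelines may run a little
#'   further so the noisy measured series also crosses the threshold).
#' @return An object of class `tissue_run`: list with `trajectory` (data frame
#'   `day`, `n_live`, `new_deaths`, `new_repairs`, `G`), `censored`, `state`
#'   (final), `positions`, `alive_at` (list, if `record_states`), `params`,
#'   `competences`.
#' @export
simulate_tissue <- function(params, competences = NULL, media_in = NULL,
                            record_times = NULL, record_states = FALSE,
                            positions = NULL, graph = NULL, stop_frac = 0.02) {
  stopifnot(inherits(params, "model_params"))
  with_seed(params$seed, {
    if (is.null(positions)) positions <- place_cells(params$n_cells, params$geometry)
    if (is.null(graph)) graph <- build_interaction_graph(positions, params$lambda_int)
    state <- tissue_state(positions, competences)
    n0 <- state$n_cells
    dt <- params$dt
    steps_per_day <- round(1 / dt)
    daily_grid <- abs(steps_per_day * dt - 1) < 1e-9
    if (!is.null(media_in) && !daily_grid) {
      stop("media_in requires dt to divide one day", call. = FALSE)
    }
    n_steps <- ceiling(params$t_max / dt - 1e-9)
    rec <- if (is.null(record_times)) (0:n_steps) * dt else sort(unique(record_times))
    rec_i <- 1L

    # incoming media at day 0
    if (!is.null(media_in) && length(media_in) >= 1) state$G <- media_in[1]

    days <- numeric(0); n_live <- integer(0); new_deaths <- integer(0)
    new_repairs <- integer(0); G_rec <- numeric(0)
    pend_deaths <- 0L; pend_repairs <- 0L
    record_row <- function(day) {
      days[length(days) + 1L] <<- day
      n_live[length(n_live) + 1L] <<- sum(state$alive)
      new_deaths[length(new_deaths) + 1L] <<- pend_deaths
      new_repairs[length(new_repairs) + 1L] <<- pend_repairs
      G_rec[length(G_rec) + 1L] <<- state$G
      pend_deaths <<- 0L; pend_repairs <<- 0L
    }
    alive_at <- if (record_states) vector("list", length(rec)) else NULL
    maybe_record <- function() {
      while (rec_i <= length(rec) && rec[rec_i] <= state$day + 1e-9) {
        record_row(rec[rec_i])
        if (record_states) alive_at[[rec_i]] <<- state$alive
        rec_i <<- rec_i + 1L
      }
    }
    maybe_record()  # day 0

    censored <- FALSE
    for (k in seq_len(n_steps)) {
      if (sum(state$alive) <= stop_frac * n0) break
      if (!is.null(media_in) && k > 1 && (k - 1) %% steps_per_day == 0) {
        idx <- (k - 1) %/% steps_per_day + 1L
        if (idx <= length(media_in)) state$G <- media_in[idx]
      }
      before <- state$alive
      state <- step_day(state, graph, params)
      pend_deaths <- pend_deaths + sum(before & !state$alive)
      pend_repairs <- pend_repairs + sum(!before & state$alive)
      maybe_record()
      if (k == n_steps && sum(state$alive) > stop_frac * n0) censored <- TRUE
    }
    if (rec_i > 1L) {
      keep <- seq_len(rec_i - 1L)
      if (record_states) alive_at <- alive_at[keep]
    }
    traj <- data.frame(day = days, n_live = n_live, new_deaths = new_deaths,
                       new_repairs = new_repairs, G = G_rec)
    structure(
      list(trajectory = traj, censored = censored, state = state,
           positions = positions,
           alive_at = alive_at, record_times = traj$day,
           params = params, competences = competences),
      class = "tissue_run"
    )
  })
}

#' @export
print.tissue_run <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(
    "Tissue run: n0 = %d, %d recorded times, final day %.3g (%s), final n = %d\n",
    tr$n_live[1], nrow(tr), tr$day[nrow(tr)],
    if (x$censored) "right-censored" else "dead", tr$n_live[nrow(tr)]
  ))
  invisible(x)
}
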