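#' Construct geometry of a hydrogel tissue slab
#'
#' The synthetic tissues are thin hydrogel slabs cast between spacers: a fixed
#' total volume spread over a fixed thickness, so the footprint area is derived
#' as volume / thickness. The footprint is modelled as a square.
#'
#' @param volume_ul Total construct volume in microliters (default 5).
#' @param thickness_um Slab thickness in micrometers (default 100).
#' @return An object of class `construct_geometry` with fields `volume_ul`,
#'   `thickness_um`, `footprint_area_mm2`, and the square footprint side
#'   lengths `lx_um`, `ly_um`.
#' @examples
#' geom <- construct_geometry()
#' geom$footprint_area_mm2  # 5 mm^3 / 0.1 mm = 50 mm^2
#' @export
construct_geometry <- function(volume_ul = 5, thickness_um = 100) {
  if (!is.numeric(volume_ul) || length(volume_ul) != 1 || !is.finite(volume_ul) ||
      volume_ul <= 0) {
    stop("invalid geometry: volume_ul must be a positive number", call. = FALSE)
  }
  if (!is.numeric(thickness_um) || length(thickness_um) != 1 ||
      !is.finite(thickness_um) || thickness_um <= 0) {
    stop("invalid geometry: thickness_um must be a positive number", call. = FALSE)
  }
  volume_mm3 <- volume_ul            # 1 uL == 1 mm^3
  thickness_mm <- thickness_um / 1000
  area_mm2 <- volume_mm3 / thickness_mm
  side_um <- sqrt(area_mm2) * 1000
  structure(
    list(
      volume_ul = volume_ul,
      thickness_um = thickness_um,
      footprint_area_mm2 = area_mm2,
      lx_um = side_um,
      ly_um = side_um
    ),
    class = "construct_geometry"
  )
}

#' @export
print.construct_geometry <- function(x, ...) {
  cat(sprintf(
    "Construct geometry: %.3g uL, %.4g um thick, footprint %.4g mm^2 (%.0f x %.0f um)\n",
    x$volume_ul, x$thickness_um, x$footprint_area_mm2, x$lx_um, x$ly_um
  ))
  invisible(x)
}

#' Simulation parameters for the interdependent-failure model
#'
#' Bundles the per-cell damage/repair rates, the cooperative-support model and
#' the integration settings of the cell-failure simulator. All rates are per
#' day; positions and radii are in micrometers.
#'
#' @param n_cells Number of cells encapsulated in the construct.
#' @param geometry A [construct_geometry()].
#' @param d Intrinsic daily failure probability of a functional cell. May be a
#'   vector of length `n_cells` for heterogeneous populations.
#' @param r Daily repair probability of a failed cell. Default 0: the hydrogel
#'   is non-degradable, cells neither divide nor migrate, and dead cells stay
#'   dead.
#' @param sigma Stress multiplier on `d` (>= 1; oxidative stress raises the
#'   intrinsic failure probability).
#' @param lambda_int Interaction radius in micrometers: cells within this
#'   distance exchange local cooperative support.
#' @param theta Minimum functional-neighbor fraction below which a connected
#'   functional cell fails in the cascade sweep (0 disables cascades).
#' @param beta Strength of the hazard reduction conferred by cooperative
#'   support (0 disables cooperative hazard modulation).
#' @param w_global Weight of the shared-medium factor level G in the support.
#' @param delta Daily decay fraction of the medium factor.
#' @param n_ref Reference cell number normalizing medium production: the
#'   factor concentration a construct builds up scales with how many cells
#'   secrete into the (fixed) media volume, so influx is
#'   `sum(p_i)/n_ref` with `n_ref` the dense 100 K construct by default.
#'   Sparse tissues therefore condition their media ~100x less, per the
#'   premise that density controls the degree of secreted-factor
#'   communication.
#' @param dt Days per step (default 1; 1 K tissues are imaged sub-daily and
#'   use dt = 1/12, i.e. 2-hour steps).
#' @param t_max Maximum simulated time in days.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `model_params`.
#' @export
model_params <- function(n_cells,
                         geometry = construct_geometry(),
                         d = 0.45,
                         r = 0,
                         sigma = 1,
                         lambda_int = 35,
                         theta = 0.02,
                         beta = 2,
                         w_global = 2.5,
                         delta = 0.1,
                         n_ref = 1e5,
                         dt = 1,
                         t_max = 60,
                         seed = NULL) {
  stopifnot(inherits(geometry, "construct_geometry"))
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 0 ||
      n_cells != round(n_cells)) {
    stop("n_cells must be a non-negative integer", call. = FALSE)
  }
  if (any(d < 0) || any(d > 1)) stop("d must lie in [0, 1]", call. = FALSE)
  if (r < 0 || r > 1) stop("r must lie in [0, 1]", call. = FALSE)
  if (sigma < 1) stop("sigma must be >= 1", call. = FALSE)
  if (any(d * sigma > 1)) stop("d * sigma must not exceed 1", call. = FALSE)
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]", call. = FALSE)
  if (lambda_int < 0) stop("lambda_int must be >= 0", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (w_global < 0) stop("w_global must be >= 0", call. = FALSE)
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  if (n_ref <= 0) stop("n_ref must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  structure(
    list(
      n_cells = as.integer(n_cells), geometry = geometry, d = d, r = r,
      sigma = sigma, lambda_int = lambda_int, theta = theta, beta = beta,
      w_global = w_global, delta = delta, n_ref = n_ref, dt = dt,
      t_max = t_max,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Model parameters: n_cells=%d, d=%s, r=%g, sigma=%g,\n",
      "  lambda_int=%g um, theta=%g, beta=%g, w_global=%g, delta=%g,\n",
      "  dt=%g d, t_max=%g d, seed=%s\n"
    ),
    x$n_cells,
    if (length(x$d) == 1) format(x$d) else sprintf("<%d values>", length(x$d)),
    x$r, x$sigma, x$lambda_int, x$theta, x$beta, x$w_global, x$delta,
    x$dt, x$t_max, if (is.null(x$seed)) "NULL" else format(x$seed)
  ))
  invisible(x)
}

#' Derive a stream seed from a top-level seed by a fixed offset
#'
#' Replicates, placements and noise draws all use seeds derived at distinct
#' fixed offsets from one top-level seed, so whole experiments are
#' reproducible from a single integer. The result is kept below 2^31.
#'
#' @param seed Top-level integer seed.
#' @param offset Fixed stream offset (non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * as.double(offset)) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. NULL seed = use current state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
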