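#' Estimated cell-cell spacing from construct volume and cell number
#'
#' For a uniform distribution the typical spacing is the cube root of the
#' volume per cell. The raw value is also reported rounded to the nearest
#' 5 um (ties rounded up), the convention under which a 5-uL construct gives
#' 170, 80 and 35 um for 1 K, 10 K and 100 K cells.
#'
#' @param volume_ul Construct volume in microliters (> 0).
#' @param n_cells Number of cells (>= 1).
#' @return List of class `spacing_estimate`: `raw_um`, `rounded_um`,
#'   `volume_ul`, `n_cells`.
#' @examples
#' estimated_spacing(5, 1e4)$rounded_um  # 80
#' @export
estimated_spacing <- function(volume_ul, n_cells) {
  if (volume_ul <= 0) stop("volume_ul must be > 0", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  raw <- (volume_ul * 1e9 / n_cells)^(1 / 3)  # uL -> um^3
  structure(
    list(raw_um = raw, rounded_um = floor(raw / 5 + 0.5) * 5,
         volume_ul = volume_ul, n_cells = n_cells),
    class = "spacing_estimate"
  )
}

#' @export
print.spacing_estimate <- function(x, ...) {
  cat(sprintf("Estimated cell-cell spacing: %.1f um (reported %g um) for %g cells in %g uL\n",
              x$raw_um, x$rounded_um, x$n_cells, x$volume_ul))
  invisible(x)
}

# 2-D nearest-neighbor distances within one set of points, chunked all-pairs.
nn_distances_2d <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(numeric(0))
  out <- numeric(n)
  chunk <- max(1, floor(2e6 / n))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1)
    dx <- outer(xy[idx, 1], xy[, 1], "-")
    dy <- outer(xy[idx, 2], xy[, 2], "-")
    d2 <- dx * dx + dy * dy
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Per-plane nearest-neighbor distance distribution
#'
#' Mimics the measurement of cell-cell distances from individual z-slices:
#' cells are binned by z, and within each slice every cell contributes its
#' 2-D (x, y) distance to the nearest other cell in the same slice. Cells
#' alone in a slice contribute nothing.
#'
#' @param positions `n x 3` matrix of positions (um).
#' @param slice_edges z boundaries of the slices (e.g. from
#'   [assign_footprints()], default ten 10-um slices over a 100-um slab).
#' @param breaks Histogram breaks passed to [graphics::hist()] binning
#'   (default `"Sturges"`).
#' @return List of class `distance_distribution`: `distances` (um), `mean`,
#'   `sd`, `n`, `histogram` (list `breaks`, `counts`).
#' @export
per_plane_nn <- function(positions, slice_edges = seq(0, 100, by = 10),
                         breaks = "Sturges") {
  if (is.data.frame(positions)) positions <- as.matrix(positions)
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  zbin <- findInterval(positions[, 3], slice_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  dists <- numeric(0)
  for (b in sort(unique(zbin))) {
    sel <- zbin == b
    if (sum(sel) >= 2) {
      dists <- c(dists, nn_distances_2d(positions[sel, 1:2, drop = FALSE]))
    }
  }
  if (!length(dists)) {
    stop("empty distribution: no slice contains at least 2 cells",
         call. = FALSE)
  }
  h <- graphics::hist(dists, breaks = breaks, plot = FALSE)
  structure(
    list(distances = dists, mean = mean(dists), sd = stats::sd(dists),
         n = length(dists), histogram = list(breaks = h$breaks,
                                             counts = h$counts)),
    class = "distance_distribution"
  )
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("Per-plane nearest-neighbor distances: %.1f +/- %.1f um (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Write a distance distribution's artifacts
#'
#' Writes `distances.csv` (one distance per row), `histogram.tsv` (bin left
#' edge, right edge, count) and `summary.json` (mean, sd, n) to a directory.
#'
#' @param dist A `distance_distribution` from [per_plane_nn()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_distance_outputs <- function(dist, dir) {
  stopifnot(inherits(dist, "distance_distribution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(distance_um = dist$distances),
                   file.path(dir, "distances.csv"), row.names = FALSE)
  br <- dist$histogram$breaks
  utils::write.table(
    data.frame(bin_left_um = br[-length(br)], bin_right_um = br[-1],
               count = dist$histogram$counts),
    file.path(dir, "histogram.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  jsonlite::write_json(list(mean_um = dist$mean, sd_um = dist$sd, n = dist$n),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Subsample cells as seen from a few imaging points
#'
#' Returns the cells falling inside a handful of disjoint, randomly placed
#' square fields of view, mimicking distance estimation from z-stacks taken
#' at a few points of the construct.
#'
#' @param positions `n x 3` matrix of positions (um).
#' @param geometry A [construct_geometry()].
#' @param n_points Number of fields (default 5).
#' @param fov_fraction Footprint-area fraction per field (default 1/16;
#'   five disjoint axis-aligned 1/8-area squares cannot be packed into the
#'   footprint, and the confocal distance fields are smaller than the
#'   dead-cell counting fields).
#' @param seed Integer seed for field placement.
#' @return List with `positions` (subsampled matrix) and `footprints`.
#' @export
sample_imaging_points <- function(positions, geometry = construct_geometry(),
                                  n_points = 5, fov_fraction = 1 / 16,
                                  seed = NULL) {
  if (is.data.frame(positions)) positions <- as.matrix(positions)
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  fp <- place_footprints(geometry, n_points, fov_fraction, seed)
  inside <- rep(FALSE, nrow(positions))
  for (k in seq_len(n_points)) {
    inside <- inside |
      (positions[, 1] >= fp[k, "x0"] & positions[, 1] <= fp[k, "x1"] &
       positions[, 2] >= fp[k, "y0"] & positions[, 2] <= fp[k, "y1"])
  }
  list(positions = positions[inside, , drop = FALSE], footprints = fp)
}
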