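#' Place cells uniformly at random inside the construct
#'
#' Cells are mixed homogeneously into the hydrogel precursor before
#' crosslinking, so positions are modelled as independent uniform draws inside
#' the slab.
#'
#' @param n Number of cells.
#' @param geometry A [construct_geometry()].
#' @param seed Integer seed for reproducible placement (`NULL` = current RNG).
#' @return An `n x 3` numeric matrix of positions (columns `x_um`, `y_um`,
#'   `z_um`).
#' @examples
#' pos <- place_cells(1000, construct_geometry(), seed = 1)
#' range(pos[, "z_um"])  # within [0, 100]
#' @export
place_cells <- function(n, geometry = construct_geometry(), seed = NULL) {
  stopifnot(inherits(geometry, "construct_geometry"))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  pos <- with_seed(seed, {
    cbind(
      x_um = stats::runif(n, 0, geometry$lx_um),
      y_um = stats::runif(n, 0, geometry$ly_um),
      z_um = stats::runif(n, 0, geometry$thickness_um)
    )
  })
  if (n == 0) pos <- matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  pos
}

#' Build the cell-cell interaction graph
#'
#' Two cells interact if their Euclidean distance is at most `lambda_int`.
#' The adjacency is computed with a uniform-grid fixed-radius search whose
#' result is identical to the all-pairs computation, but scales to 1e5 cells.
#'
#' @param positions Numeric matrix of cell positions (columns x, y, z in um).
#' @param lambda_int Interaction radius in micrometers (>= 0).
#' @return An object of class `interaction_graph` with fields `n`, `edges`
#'   (2-column matrix of 1-based index pairs, i < j), `degree` and `adjacency`
#'   (a sparse symmetric pattern matrix).
#' @export
build_interaction_graph <- function(positions, lambda_int) {
  if (is.data.frame(positions)) positions <- as.matrix(positions)
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (lambda_int < 0) stop("lambda_int must be >= 0", call. = FALSE)
  n <- nrow(positions)
  storage.mode(positions) <- "double"
  edges <- .radius_pairs_cpp(positions, lambda_int)
  colnames(edges) <- c("i", "j")
  if (nrow(edges) > 1) {
    ord <- order(edges[, 1], edges[, 2])
    edges <- edges[ord, , drop = FALSE]
  }
  adj <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]),
    j = c(edges[, 2], edges[, 1]),
    x = 1,
    dims = c(n, n)
  )
  degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  structure(
    list(n = n, edges = edges, degree = degree, adjacency = adj,
         lambda_int = lambda_int),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "Interaction graph: %d cells, %d edges (radius %g um), mean degree %.3g\n",
    x$n, nrow(x$edges), x$lambda_int, mean(x$degree)
  ))
  invisible(x)
}
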