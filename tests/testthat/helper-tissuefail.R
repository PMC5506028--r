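# Small-construct helpers so interaction-heavy tests stay fast: a 0.05-uL
# slab at 2000 cells has the same density (hence mean degree) as the full
# 5-uL construct at 100 K cells.
small_geometry <- function() construct_geometry(volume_ul = 0.05,
                                                thickness_um = 100)

small_dense_params <- function(n = 2000, seed = 1, ...) {
  model_params(n_cells = n, geometry = small_geometry(), seed = seed, ...)
}

# Brute-force nearest-neighbor mean for a point matrix (any dimension),
# chunked to bound memory; used as an independent oracle.
brute_nn_mean <- function(pts) {
  n <- nrow(pts)
  mins <- numeric(n)
  chunk <- max(1, floor(2e6 / n))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1)
    d2 <- matrix(0, length(idx), n)
    for (k in seq_len(ncol(pts))) {
      d2 <- d2 + outer(pts[idx, k], pts[, k], "-")^2
    }
    d2[cbind(seq_along(idx), idx)] <- Inf
    mins[idx] <- sqrt(apply(d2, 1, min))
  }
  mean(mins)
}

# Fully exhaustive imaging protocol: one stack covering the whole gel,
# counted on the maximum projection, perfect detection.
exhaustive_protocol <- function() {
  imaging_protocol(n_stacks = 1, stack_fov_fraction = 1,
                   mode = "max_projection", detection_gain = 1)
}
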