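test_that("imaging protocol validates its geometry fractions", {
  p <- imaging_protocol()
  expect_equal(p$n_stacks * p$stack_fov_fraction, 3 / 8)
  expect_error(imaging_protocol(n_stacks = 9, stack_fov_fraction = 1 / 8),
               "exceeds 1")
  expect_error(imaging_protocol(middle_slices = 11, n_slices = 10),
               "middle_slices")
  expect_error(imaging_protocol(detection_gain = 0), "detection_gain")
})

test_that("middle slices are the central ones for 10 and 11 slices", {
  expect_equal(middle_slice_indices(imaging_protocol(n_slices = 10)), 4:6)
  expect_equal(middle_slice_indices(imaging_protocol(n_slices = 11)), 5:7)
})

test_that("stack footprints are disjoint, correctly sized and seeded", {
  g <- construct_geometry()
  fp <- assign_footprints(g, imaging_protocol(), seed = 10)
  m <- fp$footprints
  area <- (m[, "x1"] - m[, "x0"]) * (m[, "y1"] - m[, "y0"])
  expect_equal(area / (g$footprint_area_mm2 * 1e6), rep(1 / 8, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    overlap <- m[i, "x0"] < m[j, "x1"] && m[i, "x1"] > m[j, "x0"] &&
      m[i, "y0"] < m[j, "y1"] && m[i, "y1"] > m[j, "y0"]
    expect_false(overlap)
  }
  expect_identical(fp, assign_footprints(g, imaging_protocol(), seed = 10))
  # a single full-gel stack covers the whole footprint
  full <- assign_footprints(g, exhaustive_protocol(), seed = 1)$footprints
  expect_equal(unname(full[1, c("x1", "y1")] - full[1, c("x0", "y0")]),
               c(g$lx_um, g$ly_um))
  expect_equal(length(assign_footprints(g, imaging_protocol(),
                                        seed = 2)$slice_edges), 11)
})

test_that("imaging counts new deaths in footprints, by slice", {
  g <- construct_geometry()
  pos <- place_cells(400, g, seed = 11)
  comp <- cell_competences(400, "young", senescent_frac = 0)
  prev <- tissue_state(pos, comp)
  now <- prev
  # no new deaths -> all zero
  fp <- assign_footprints(g, imaging_protocol(), seed = 3)
  rec0 <- image_day(prev, now, fp, imaging_protocol())
  expect_equal(nrow(rec0), 9)
  expect_true(all(rec0$dead_count == 0))
  # exhaustive sampling recovers the exact number of new deaths
  set.seed(12)
  now$alive[sample(400, 150)] <- FALSE
  fp1 <- assign_footprints(g, exhaustive_protocol(), seed = 4)
  rec1 <- image_day(prev, now, fp1, exhaustive_protocol())
  expect_equal(sum(rec1$dead_count), 150)
  # mismatched cell sets are rejected
  other <- tissue_state(place_cells(400, g, seed = 99), comp)
  expect_error(image_day(prev, other, fp1, exhaustive_protocol()),
               "inconsistent")
})

test_that("default 3 x 1/8 sampling is unbiased (binomial oracle)", {
  g <- construct_geometry()
  proto <- imaging_protocol(mode = "max_projection")
  comp <- cell_competences(200, "young", senescent_frac = 0)
  set.seed(14)
  # fresh uniform deaths AND fresh footprints each imaging: coverage
  # probability varies with position, so unbiasedness is over both draws
  totals <- vapply(1:200, function(i) {
    prev <- tissue_state(place_cells(200, g), comp)
    now <- prev
    now$alive[] <- FALSE  # 200 uniformly placed new deaths
    fp <- assign_footprints(g, proto)
    sum(image_day(prev, now, fp, proto)$dead_count)
  }, numeric(1))
  se <- sd(totals) / sqrt(200)
  expect_lt(abs(mean(totals) - 200 * 3 / 8), 3 * se)
})

test_that("detection gain thins counts and Poisson jitter preserves the mean", {
  g <- construct_geometry()
  pos <- place_cells(500, g, seed = 15)
  comp <- cell_competences(500, "young", senescent_frac = 0)
  prev <- tissue_state(pos, comp)
  now <- prev; now$alive[] <- FALSE
  proto <- imaging_protocol(n_stacks = 1, stack_fov_fraction = 1,
                            mode = "max_projection", detection_gain = 0.5)
  fp <- assign_footprints(g, proto, seed = 1)
  set.seed(16)
  counts <- vapply(1:300, function(i) sum(image_day(prev, now, fp, proto)$dead_count),
                   numeric(1))
  expect_lt(abs(mean(counts) - 250), 3 * sd(counts) / sqrt(300))
  protoP <- imaging_protocol(n_stacks = 1, stack_fov_fraction = 1,
                             mode = "max_projection", count_noise = "poisson")
  set.seed(17)
  countsP <- vapply(1:300, function(i) sum(image_day(prev, now, fp, protoP)$dead_count),
                    numeric(1))
  expect_lt(abs(mean(countsP) - 500), 3 * sd(countsP) / sqrt(300))
})

test_that("the 1 K schedule adds the sub-daily first-day stainings", {
  s <- imaging_schedule("1K", 3)
  expect_equal(s[1:6], c(0, 2, 4, 6, 20, 24) / 24)
  expect_equal(s[-(1:6)], 2:3)
  expect_equal(imaging_schedule("100K", 3), 0:3)
})

test_that("generated experiments have per-replicate records, seeds and conserved truth", {
  sc <- scenario_config(density = "1K", age_class = "young", replicates = 3,
                        seed = 91)
  ex <- generate_experiment(sc)
  expect_equal(sort(unique(ex$records$replicate)), 1:3)
  # distinct derived seeds give distinct record streams
  r1 <- ex$records[ex$records$replicate == 1, "dead_count"]
  r2 <- ex$records[ex$records$replicate == 2, "dead_count"]
  expect_false(identical(r1, r2))
  for (run in ex$truth) {
    tr <- run$trajectory
    expect_equal(sum(tr$new_deaths), tr$n_live[1] - tr$n_live[nrow(tr)])
  }
  # records serialize losslessly
  tmp <- tempfile(fileext = ".tsv")
  write_records(ex$records, tmp)
  back <- read_records(tmp)
  expect_equal(back$dead_count, ex$records$dead_count)
  expect_equal(back$time_h, ex$records$time_h)
  unlink(tmp)
})
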