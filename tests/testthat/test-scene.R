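test_that("isotropic orientation model has pitch CDF sin(theta)", {
  spec <- scene_spec(extent_um = c(60, 60, 12), cell_count = 20000,
                     orientation_model = "isotropic",
                     overlap_policy = "allow", seed = 5)
  cells <- sample_scene(spec)
  p <- cell_pitches(cells)
  n <- length(p)
  for (theta in c(15, 30, 45, 60)) {
    expected <- sin(theta * pi / 180)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(p < theta) - expected), 3 * se)
  }
  # headline null: half the cells below 30 degrees
  expect_equal(mean(p < 30), 0.5, tolerance = 0.02)
})

test_that("layered orientation model matches the half-normal law", {
  spec <- scene_spec(extent_um = c(60, 60, 12), cell_count = 20000,
                     orientation_model = "layered", pitch_sigma_deg = 19.8,
                     overlap_policy = "allow", seed = 6)
  p <- cell_pitches(sample_scene(spec))
  # sub-30-degree mass: 2*Phi(30/sigma) - 1
  expect_equal(mean(p < 30), 2 * pnorm(30 / 19.8) - 1, tolerance = 0.01)
  # steep cells are rare: tail above 45 degrees under sigma <= 20
  expect_lt(mean(p > 45), 0.03)
  expect_equal(mean(p > 45), 2 * pnorm(-45 / 19.8), tolerance = 0.01)
  # mean of a half-normal is sigma * sqrt(2/pi)
  expect_equal(mean(p), 19.8 * sqrt(2 / pi), tolerance = 0.25)
})

test_that("layered centroids are quantized to layers", {
  spec <- scene_spec(extent_um = c(40, 40, 12), cell_count = 200,
                     orientation_model = "layered", pitch_sigma_deg = 10,
                     layer_spacing_um = 1.0, overlap_policy = "allow",
                     seed = 7)
  cells <- sample_scene(spec)
  offs <- abs(cells$z_um - round(cells$z_um / 1.0) * 1.0)
  expect_lte(max(offs), 0.1 + 1e-9)  # jitter bounded by 10 % of the spacing
})

test_that("scene sampling is deterministic given the seed", {
  spec <- scene_spec(cell_count = 30, seed = 11)
  expect_identical(sample_scene(spec), sample_scene(spec))
  spec2 <- scene_spec(cell_count = 30, seed = 12)
  expect_false(identical(sample_scene(spec)$x_um, sample_scene(spec2)$x_um))
})

test_that("reject policy guarantees pairwise clearance", {
  spec <- scene_spec(extent_um = c(30, 30, 10), cell_count = 60, seed = 8,
                     min_gap_um = 0.5, max_placement_attempts = 2000)
  cells <- sample_scene(spec)
  # brute-force: sample points along each axis segment, check all pairs
  pts <- lapply(seq_len(nrow(cells)), function(i) {
    hl <- cells$length_um[i] / 2 - cells$diameter_um[i] / 2
    tt <- seq(-hl, hl, length.out = 40)
    cbind(cells$x_um[i] + tt * cells$axis_x[i],
          cells$y_um[i] + tt * cells$axis_y[i],
          cells$z_um[i] + tt * cells$axis_z[i])
  })
  min_d <- Inf
  for (i in 1:(nrow(cells) - 1)) for (j in (i + 1):nrow(cells)) {
    d2 <- outer(rowSums(pts[[i]]^2), rowSums(pts[[j]]^2), "+") -
      2 * pts[[i]] %*% t(pts[[j]])
    min_d <- min(min_d, sqrt(max(0, min(d2))))
  }
  expect_gte(min_d, cells$diameter_um[1] + 0.5 - 1e-6)
})

test_that("overcrowded domains fail with an informative placement error", {
  spec <- scene_spec(extent_um = c(10, 10, 12), cell_count = 500, seed = 9,
                     length_range_um = c(3, 5), max_placement_attempts = 25)
  expect_error(sample_scene(spec), "25 attempts")
})

test_that("cells lie entirely inside the domain with z >= 0", {
  spec <- scene_spec(extent_um = c(30, 30, 12), cell_count = 100,
                     orientation_model = "isotropic",
                     overlap_policy = "allow", seed = 10)
  cells <- sample_scene(spec)
  hl <- cells$length_um / 2 - cells$diameter_um / 2
  zlo <- cells$z_um - (hl * abs(cells$axis_z) + cells$diameter_um / 2)
  zhi <- cells$z_um + (hl * abs(cells$axis_z) + cells$diameter_um / 2)
  expect_true(all(zlo >= -1e-9))
  expect_true(all(zhi <= 12 + 1e-9))
  expect_true(all(cells$axis_z >= 0))
  nrm <- sqrt(cells$axis_x^2 + cells$axis_y^2 + cells$axis_z^2)
  expect_equal(nrm, rep(1, nrow(cells)), tolerance = 1e-9)
})
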