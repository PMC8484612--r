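test_that("a blank stack segments to zero labels", {
  spec <- scene_spec(extent_um = c(10, 10, 5), cell_count = 0, seed = 1)
  truth <- rasterize_cells(sample_scene(spec), spec)
  st <- render_stack(truth, imaging_spec(seed = 1), ri_interface(1.33, 1.333))
  labels <- segment_cells(st, seg_imm())
  expect_identical(labels$n_labels, 0L)
  m <- measure_cells(labels)
  expect_identical(nrow(m), 0L)
  expect_identical(angle_summary(m$pitch_deg)$n, 0L)
})

test_that("well-separated cells are recovered one label each, Jaccard >= 0.8", {
  spec <- scene_spec(extent_um = c(30, 30, 8), cell_count = 5, seed = 13,
                     min_gap_um = 2, max_placement_attempts = 2000)
  sim <- simulate_stack(spec, noise_free(imaging_spec()))
  labels <- segment_cells(sim$stack, seg_imm())
  expect_identical(labels$n_labels, 5L)
  est <- labels$data
  tru <- sim$truth$labels$data
  for (id in sim$truth$cells$id) {
    tv <- tru == id
    est_id <- names(which.max(table(est[tv])))
    ev <- est == as.integer(est_id)
    jac <- sum(ev & tv) / sum(ev | tv)
    expect_gte(jac, 0.8)
  }
})

test_that("segmentation is deterministic and monotone in min_volume", {
  sim <- small_layered_sim()
  a <- segment_cells(sim$stack, seg_imm())
  b <- segment_cells(sim$stack, seg_imm())
  expect_identical(a$data, b$data)
  counts <- vapply(c(0, 0.5, 2, 5, 20),
                   function(v) segment_cells(sim$stack, seg_imm(min_volume_um3 = v))$n_labels,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("touching cells merge into one component", {
  spec <- scene_spec(extent_um = c(10, 10, 4), voxel_size_um = c(0.1, 0.1, 0.1),
                     cell_count = 0, overlap_policy = "allow", seed = 1)
  cells <- data.frame(id = 1:2, x_um = c(3.6, 6.4), y_um = 5, z_um = 2,
                      length_um = 4, diameter_um = 0.8,
                      axis_x = 1, axis_y = 0, axis_z = 0,
                      reflectivity = 1)
  truth <- rasterize_cells(cells, spec)
  st <- render_stack(truth, noise_free(imaging_spec()),
                     ri_interface(1.333, 1.333))
  labels <- segment_cells(st, seg_imm())
  expect_identical(labels$n_labels, 1L)
})

test_that("label count equals true count on >= 95% of separated scenes", {
  ok <- 0L
  n_scenes <- 20L
  for (s in seq_len(n_scenes)) {
    spec <- scene_spec(extent_um = c(32, 32, 8), cell_count = 30,
                       seed = 100 + s, min_gap_um = 0.8,
                       max_placement_attempts = 2000)
    sim <- simulate_stack(spec, noise_free(imaging_spec(seed = 100 + s)))
    labels <- segment_cells(sim$stack, seg_imm())
    if (labels$n_labels == 30L) ok <- ok + 1L
  }
  expect_gte(ok / n_scenes, 0.95)
})

test_that("labels are consecutive and ordered by first voxel", {
  sim <- small_layered_sim()
  labels <- segment_cells(sim$stack, seg_imm())
  expect_gt(labels$n_labels, 0L)
  present <- sort(unique(as.integer(labels$data[labels$data > 0])))
  expect_identical(present, seq_len(labels$n_labels))
  # component k's minimal (z, y, x) is non-decreasing in k
  idx <- which(labels$data > 0)
  ai <- arrayInd(idx, dim(labels$data))
  li <- labels$data[idx]
  minz <- tapply(ai[, 3], li, min)
  miny <- tapply(ai[, 1], li, min)
  minx <- tapply(ai[, 2], li, min)
  key <- order(minz, miny, minx)
  expect_identical(key, seq_along(key))
})

test_that("excluded interface slices are background but retained in shape", {
  sim <- small_layered_sim()
  labels <- segment_cells(sim$stack, segmentation_params(
    exclude_slices_below_um = 2))
  expect_identical(dim(labels$data), dim(sim$stack$data))
  zs <- z_coords(sim$stack)
  expect_true(all(labels$data[, , zs < 2] == 0L))
})

test_that("background estimation recovers configured operating points", {
  # constant stack: exact
  const <- zstack(array(123.4, dim = c(8, 8, 5)), c(0.2, 0.2, 0.2), 2L)
  expect_identical(estimate_background(const, 0.4), 123.4)
  # index-matched render at baseline 86.2 with sparse cells
  spec <- scene_spec(extent_um = c(20, 20, 6), cell_count = 10, seed = 17,
                     min_gap_um = 0.8, max_placement_attempts = 1000)
  truth <- rasterize_cells(sample_scene(spec), spec)
  st <- render_stack(truth, noise_free(imaging_spec(baseline_au = 86.2)),
                     ri_interface(1.33, 1.333))
  expect_equal(estimate_background(st, 1), 86.2, tolerance = 0.5)
  # empty stage at baseline 86.4
  empty_spec <- scene_spec(extent_um = c(10, 10, 4), cell_count = 0, seed = 1)
  empty <- rasterize_cells(sample_scene(empty_spec), empty_spec)
  st2 <- render_stack(empty, noise_free(imaging_spec(baseline_au = 86.4)),
                      ri_interface(1.333, 1.333))
  expect_equal(estimate_background(st2, 1), 86.4, tolerance = 1e-6)
  expect_error(estimate_background(st2, 100), "outside")
})

test_that("Otsu threshold maximizes the between-class variance", {
  set.seed(1)
  v <- c(rnorm(5000, 100, 5), rnorm(500, 1000, 30))
  thr <- otsu_threshold(v)
  # independent oracle: direct grid search over candidate thresholds
  cand <- seq(min(v), max(v), length.out = 2000)
  bc <- vapply(cand, function(t) {
    w1 <- mean(v <= t)
    if (w1 == 0 || w1 == 1) return(0)
    (mean(v[v <= t]) - mean(v[v > t]))^2 * w1 * (1 - w1)
  }, 0)
  expect_equal(thr, cand[which.max(bc)], tolerance = 0.05)
  expect_identical(otsu_threshold(rep(7, 100)), 7)
})
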