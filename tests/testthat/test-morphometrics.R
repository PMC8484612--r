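test_that("pitch angle is arcsin(|z|), sign-invariant, range [0, 90]", {
  expect_identical(pitch_angle(c(1, 0, 0)), 0)
  expect_identical(pitch_angle(c(0, 0, 1)), 90)
  expect_equal(pitch_angle(c(1, 0, 1) / sqrt(2)), 45)
  set.seed(3)
  for (i in 1:50) {
    v <- rnorm(3)
    expect_equal(pitch_angle(v), pitch_angle(-v))
    expect_gte(pitch_angle(v), 0)
    expect_lte(pitch_angle(v), 90)
  }
  expect_error(pitch_angle(c(0, 0, 0)), "nonzero")
})

test_that("principal axis recovers spherocylinder orientation within 2 deg", {
  for (true_pitch in c(0, 15, 30, 45, 60, 75)) {
    truth <- single_cell_truth(true_pitch, yaw_deg = 30)
    m <- measure_cells(truth$labels)
    expect_identical(nrow(m), 1L)
    expect_false(m$flag_isotropic)
    expect_lt(abs(m$pitch_deg - true_pitch), 2)
  }
  # vertical cell
  truth <- single_cell_truth(90)
  m <- measure_cells(truth$labels)
  expect_gte(m$pitch_deg, 88)
  expect_equal(abs(m$axis_z), 1, tolerance = 1e-2)
})

test_that("a cube of voxels is flagged isotropic", {
  coords <- as.matrix(expand.grid(x = (1:10) * 0.1, y = (1:10) * 0.1,
                                  z = (1:10) * 0.1))
  pa <- principal_axis(coords)
  expect_false(pa$degenerate)
  expect_equal(pa$eigenvalues[1], pa$eigenvalues[3], tolerance = 1e-9)
  lab <- array(0L, dim = c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L
  vol <- structure(list(data = lab, voxel_size = c(0.1, 0.1, 0.1),
                        z_origin = 1L, n_labels = 1L),
                   class = "label_volume")
  m <- measure_cells(vol)
  expect_true(m$flag_isotropic)
  expect_true(is.na(m$pitch_deg))
  expect_identical(angle_summary(m$pitch_deg)$n, 0L)
})

test_that("degenerate components are flagged and excluded", {
  expect_true(principal_axis(matrix(runif(9), 3, 3))$degenerate)  # < 4 voxels
  flat <- cbind(runif(10), runif(10), 0.5)                        # coplanar
  expect_true(principal_axis(flat)$degenerate)
})

test_that("angle summary reports mean and threshold fractions", {
  s <- angle_summary(c(10, 20, 40), 30)
  expect_equal(s$mean_deg, 23.3333, tolerance = 1e-4)
  expect_equal(unname(s$fraction_below), 2 / 3)
  z <- angle_summary(rep(0, 5), c(10, 30))
  expect_identical(z$mean_deg, 0)
  expect_true(all(z$fraction_below == 1))
  e <- angle_summary(numeric(0))
  expect_identical(e$n, 0L)
  expect_true(is.na(e$mean_deg))
  expect_true(all(is.na(e$fraction_below)))
  expect_error(angle_summary(c(10, 95)), "0, 90")
})

test_that("occupancy profile matches the rasterization oracle after rendering", {
  sim <- small_layered_sim()
  roi <- colony_roi(sim$truth$labels)
  labels <- segment_cells(sim$stack, seg_imm())
  occ_est <- occupancy_profile(labels, roi)
  occ_true <- occupancy_profile(sim$truth$labels, roi)
  expect_equal(occ_est$z_um, occ_true$z_um)
  expect_lte(max(abs(occ_est$occupancy - occ_true$occupancy)), 0.02)
})

test_that("occupancy handles full, empty and invalid ROIs", {
  lab <- array(1L, dim = c(10, 10, 3))
  vol <- structure(list(data = lab, voxel_size = c(0.2, 0.2, 0.2),
                        z_origin = 1L, n_labels = 1L),
                   class = "label_volume")
  occ <- occupancy_profile(vol, matrix(TRUE, 10, 10))
  expect_true(all(occ$occupancy == 1))
  expect_true(all(diff(occ$z_um) > 0))
  expect_error(occupancy_profile(vol, matrix(FALSE, 10, 10)), "empty")
})

test_that("heatmap tiles conserve the field occupancy per slice", {
  sim <- small_layered_sim()
  labels <- sim$truth$labels
  heat <- density_heatmap(labels, 2.4)
  expect_true(all(heat$tiles >= 0 & heat$tiles <= 1))
  for (k in c(1, 10, 20)) {
    weighted <- sum(heat$tiles[, , k] * heat$tile_voxels) /
      sum(heat$tile_voxels)
    expect_equal(weighted, mean(labels$data[, , k] > 0), tolerance = 1e-12)
  }
  expect_error(density_heatmap(labels, 0.01), "at least one voxel")
})

test_that("a cell strictly inside one tile lights only that tile", {
  spec <- scene_spec(extent_um = c(4.8, 4.8, 3), voxel_size_um = c(0.1, 0.1, 0.1),
                     cell_count = 0, seed = 1)
  cells <- data.frame(id = 1L, x_um = 1.2, y_um = 1.2, z_um = 1.5,
                      length_um = 1.6, diameter_um = 0.8,
                      axis_x = 1, axis_y = 0, axis_z = 0, reflectivity = 1)
  truth <- rasterize_cells(cells, spec)
  heat <- density_heatmap(truth$labels, 2.4)
  for (k in seq_len(dim(heat$tiles)[3])) {
    nz <- which(heat$tiles[, , k] > 0)
    if (length(nz)) expect_identical(nz, 1L)   # only tile (1, 1)
  }
  expect_gt(max(heat$tiles[1, 1, ]), 0)
})

test_that("axial profile averages per slice and respects exclusions", {
  const <- zstack(array(55, dim = c(10, 10, 4)), c(0.2, 0.2, 0.2), 2L)
  prof <- axial_intensity_profile(const)
  expect_true(all(prof$mean_intensity == 55))
  # a bright corner region raises only the profile where it is bright
  arr <- array(100, dim = c(10, 10, 4))
  arr[1:3, 1:3, 2] <- 1000
  st <- zstack(arr, c(0.2, 0.2, 0.2), 2L)
  excl <- matrix(FALSE, 10, 10); excl[1:3, 1:3] <- TRUE
  with_mark <- axial_intensity_profile(st)
  without <- axial_intensity_profile(st, excl)
  expect_true(all(without$mean_intensity == 100))
  expect_gt(with_mark$mean_intensity[2], 100)
  expect_equal(with_mark$mean_intensity[-2], without$mean_intensity[-2])
  expect_error(axial_intensity_profile(st, matrix(TRUE, 10, 10)), "full field")
})

test_that("SBR is the ratio of mean cell to mean background patches", {
  arr <- array(86.2, dim = c(30, 30, 5))
  lab <- array(0L, dim = c(30, 30, 5))
  lab[5:20, 5:20, 4] <- 1L
  arr[5:20, 5:20, 4] <- 172.4
  st <- zstack(arr, c(0.2, 0.2, 0.2), 3L)
  vol <- structure(list(data = lab, voxel_size = c(0.2, 0.2, 0.2),
                        z_origin = 3L, n_labels = 1L),
                   class = "label_volume")
  sbr <- signal_background_ratio(st, vol, z_offset_um = 0.2, seed = 5)
  expect_equal(sbr$ratio, 2.0, tolerance = 1e-12)
  expect_identical(sbr$n_regions, 20L)
  # identical intensities give ratio 1
  st1 <- zstack(array(100, dim = c(30, 30, 5)), c(0.2, 0.2, 0.2), 3L)
  expect_equal(signal_background_ratio(st1, vol, 0.2, seed = 5)$ratio, 1.0)
  # deterministic given seed
  a <- signal_background_ratio(st, vol, 0.2, seed = 9)
  b <- signal_background_ratio(st, vol, 0.2, seed = 9)
  expect_identical(a$ratio, b$ratio)
  # insufficient candidates named by class
  tiny <- array(0L, dim = c(30, 30, 5)); tiny[10:12, 10:12, 4] <- 1L
  vol2 <- structure(list(data = tiny, voxel_size = c(0.2, 0.2, 0.2),
                         z_origin = 3L, n_labels = 1L),
                    class = "label_volume")
  expect_error(signal_background_ratio(st, vol2, 0.2, n_regions = 20),
               "cell patches")
})

test_that("SBR on noise-free renders matches the configured contrast", {
  spec <- scene_spec(extent_um = c(24, 24, 6), cell_count = 12, seed = 19,
                     min_gap_um = 0.8, max_placement_attempts = 1000)
  truth <- rasterize_cells(sample_scene(spec), spec)
  img <- noise_free(imaging_spec(baseline_au = 86.2,
                                 cell_intensity_scale = 86.2,
                                 psf_lateral_fwhm_um = 1e-4,
                                 psf_axial_fwhm_um = 1e-4))
  st <- render_stack(truth, img, ri_interface(1.33, 1.333))
  labels <- segment_cells(st, seg_imm())
  sbr <- signal_background_ratio(st, labels, z_offset_um = 2, seed = 7)
  expect_equal(sbr$ratio, 2.0, tolerance = 0.002)
})

test_that("colony reference slices are the 10/50/90th occupied percentiles", {
  lab <- array(0L, dim = c(6, 6, 30))
  lab[3, 3, 6:25] <- 1L
  vol <- structure(list(data = lab, voxel_size = c(0.2, 0.2, 0.2),
                        z_origin = 3L, n_labels = 1L),
                   class = "label_volume")
  refs <- colony_reference_slices(vol, matrix(TRUE, 6, 6))
  expect_identical(refs[["bottom"]], as.integer(quantile(6:25, 0.1, type = 1)))
  expect_identical(refs[["mid"]], as.integer(quantile(6:25, 0.5, type = 1)))
  expect_identical(refs[["top"]], as.integer(quantile(6:25, 0.9, type = 1)))
})
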