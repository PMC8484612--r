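# Shared fixtures, built in code. Expensive ones are memoized per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Low-noise imaging at the default operating point (the usual recovery
# condition: shot noise at 10 photons per a.u., 1 a.u. read noise).
imaging_lite <- function(seed = 1L) {
  imaging_spec(poisson_gain = 10, read_noise_sd = 1, seed = seed)
}

# Segmentation for index-matched stacks (dark interface: nothing to
# exclude near z = 0).
seg_imm <- function(...) {
  segmentation_params(exclude_slices_below_um = 0, ...)
}

# A single spherocylinder at a prescribed pitch, rasterized on an
# isotropic 0.1 um grid.
single_cell_truth <- function(pitch_deg, length_um = 6, diameter_um = 0.8,
                              yaw_deg = 0) {
  spec <- scene_spec(extent_um = c(12, 12, 9),
                     voxel_size_um = c(0.1, 0.1, 0.1),
                     cell_count = 0, seed = 1)
  p <- pitch_deg * pi / 180
  y <- yaw_deg * pi / 180
  cells <- data.frame(id = 1L, x_um = 6, y_um = 6, z_um = 4.5,
                      length_um = length_um, diameter_um = diameter_um,
                      axis_x = cos(p) * cos(y), axis_y = cos(p) * sin(y),
                      axis_z = sin(p), reflectivity = 1)
  rasterize_cells(cells, spec)
}

# Small layered scene rendered end to end (memoized).
small_layered_sim <- function() {
  memo("small_layered_sim", {
    spec <- scene_spec(extent_um = c(25, 25, 8), cell_count = 25, seed = 42,
                       orientation_model = "layered", pitch_sigma_deg = 16.8,
                       min_gap_um = 0.8, max_placement_attempts = 1000)
    simulate_stack(spec, imaging_lite(42))
  })
}
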