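#' Specification of a synthetic biofilm scene
#'
#' Describes a population of spherocylindrical (capsule-shaped) cells in a
#' rectangular liquid domain above the solid--liquid interface (z = 0), and
#' the voxel grid on which the scene will be rasterized and rendered. Two
#' orientation models are provided: `"layered"` emulates laminated
#' quasi-horizontal sheets of filamentous cells (pitch angles drawn from a
#' half-normal distribution, centroid z quantized to layers), and
#' `"isotropic"` draws cell axes uniformly on the upper unit hemisphere
#' (pitch CDF `sin(theta)`), the randomly oriented reference architecture.
#'
#' @param extent_um Domain extents `c(x, y, z)` in micrometres; cells are
#'   placed entirely inside, with z in `[0, extent_um[3]]`.
#' @param voxel_size_um Voxel pitch `c(dy, dx, dz)` in micrometres.
#' @param cell_count Number of cells to place.
#' @param orientation_model `"layered"` or `"isotropic"`.
#' @param pitch_sigma_deg Half-normal scale of the pitch distribution
#'   (layered model only; the population mean pitch is
#'   `pitch_sigma_deg * sqrt(2/pi)`).
#' @param layer_spacing_um Vertical layer quantum of the layered model;
#'   centroid z snaps to the nearest multiple plus jitter of up to 10 %.
#' @param length_range_um Tip-to-tip cell length range, sampled uniformly.
#' @param diameter_um Cell diameter.
#' @param reflectivity Dimensionless reflection amplitude per cell.
#' @param overlap_policy `"reject"` (no two capsules intersect; placement
#'   is retried) or `"allow"`.
#' @param min_gap_um Minimum surface-to-surface clearance between cells
#'   under the reject policy (0 = touching allowed). Recovery experiments
#'   that need every cell individually resolvable use about one cell
#'   diameter.
#' @param max_placement_attempts Retries per cell before giving up under
#'   the reject policy.
#' @param z_margin_below_um Depth of the rendered volume below the
#'   interface plane (into the solid), so the interface reflection peak is
#'   resolved.
#' @param seed Integer seed; scene geometry is reproducible given the seed.
#' @return An object of class `scene_spec`.
#' @examples
#' scene_spec(extent_um = c(20, 20, 8), cell_count = 10, seed = 1)
#' @export
scene_spec <- function(extent_um = c(40, 40, 12),
                       voxel_size_um = c(0.15, 0.15, 0.2),
                       cell_count = 100,
                       orientation_model = c("layered", "isotropic"),
                       pitch_sigma_deg = 16.8,
                       layer_spacing_um = 1.0,
                       length_range_um = c(3, 10),
                       diameter_um = 0.8,
                       reflectivity = 1,
                       overlap_policy = c("reject", "allow"),
                       min_gap_um = 0,
                       max_placement_attempts = 200L,
                       z_margin_below_um = 1.0,
                       seed = 1L) {
  orientation_model <- match.arg(orientation_model)
  overlap_policy <- match.arg(overlap_policy)
  extent_um <- as.numeric(extent_um)
  voxel_size_um <- as.numeric(voxel_size_um)
  length_range_um <- as.numeric(length_range_um)
  if (length(extent_um) != 3L || any(extent_um <= 0))
    stop("extent_um must be three positive lengths")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive lengths")
  if (length(length_range_um) != 2L || any(length_range_um <= 0) ||
      length_range_um[1] > length_range_um[2])
    stop("length_range_um must be 0 < min <= max")
  if (diameter_um <= 0 || length_range_um[1] < diameter_um)
    stop("need length >= diameter > 0")
  if (orientation_model == "layered" && pitch_sigma_deg <= 0)
    stop("pitch_sigma_deg must be positive for the layered model")
  if (orientation_model == "layered" && layer_spacing_um <= 0)
    stop("layer_spacing_um must be positive")
  if (cell_count < 0) stop("cell_count must be >= 0")
  if (min_gap_um < 0) stop("min_gap_um must be >= 0")
  structure(list(extent_um = extent_um, voxel_size_um = voxel_size_um,
                 cell_count = as.integer(cell_count),
                 orientation_model = orientation_model,
                 pitch_sigma_deg = pitch_sigma_deg,
                 layer_spacing_um = layer_spacing_um,
                 length_range_um = length_range_um,
                 diameter_um = diameter_um,
                 reflectivity = reflectivity,
                 overlap_policy = overlap_policy,
                 min_gap_um = min_gap_um,
                 max_placement_attempts = as.integer(max_placement_attempts),
                 z_margin_below_um = z_margin_below_um,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Minimum distance between segments (p0,p1) and each of (q0,q1)[i,].
# Vectorized closest-point-between-segments (handles point-degenerate
# segments, i.e. spherical cells).
.segment_distances <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0
  d2 <- q1 - q0
  r <- -sweep(q0, 2, p0, "-")           # p0 - q0, one row per segment
  a <- sum(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  cc <- as.numeric(r %*% d1)            # d1 . (p0 - q0)
  b <- as.numeric(d2 %*% d1)
  denom <- a * e - b^2
  s <- ifelse(denom > 1e-12, clamp((b * f - cc * e) / denom, 0, 1), 0)
  if (a <= 1e-12) s <- rep(0, length(e))
  t <- ifelse(e > 1e-12, (b * s + f) / e, 0)
  t_cl <- clamp(t, 0, 1)
  # re-project s where t was clamped (or segment 2 is a point)
  s <- ifelse((t != t_cl | e <= 1e-12) & a > 1e-12,
              clamp((b * t_cl - cc) / a, 0, 1), s)
  cp1 <- matrix(p0, nrow = length(e), ncol = 3, byrow = TRUE) + outer(s, d1)
  cp2 <- q0 + d2 * t_cl
  sqrt(rowSums((cp1 - cp2)^2))
}

.sample_axis <- function(model, pitch_sigma_deg) {
  if (model == "isotropic") {
    # uniform on the upper hemisphere: axis_z uniform in [0, 1]
    az <- runif(1)
    phi <- runif(1, 0, 2 * pi)
    r <- sqrt(max(0, 1 - az^2))
    c(r * cos(phi), r * sin(phi), az)
  } else {
    repeat {
      pitch <- abs(rnorm(1, 0, pitch_sigma_deg))
      if (pitch <= 90) break
    }
    yaw <- runif(1, 0, 2 * pi)
    p <- pitch * pi / 180
    c(cos(p) * cos(yaw), cos(p) * sin(yaw), sin(p))
  }
}

#' Sample a synthetic cell population
#'
#' Draws cell lengths, orientations and positions according to the scene's
#' orientation model. Axis and length are drawn once per cell and never
#' resampled during placement retries, so rejection sampling (overlap or
#' domain fit) does not bias the orientation distribution. Under
#' `overlap_policy = "reject"` no two capsules intersect (minimum
#' axis-segment distance >= the sum of radii).
#'
#' @param spec A [scene_spec()].
#' @return A data frame of class `cell_set` with one row per cell and
#'   columns `id, x_um, y_um, z_um, length_um, diameter_um, axis_x,
#'   axis_y, axis_z, reflectivity`; the scene spec is attached as
#'   attribute `"spec"`.
#' @export
sample_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$cell_count
  ext <- spec$extent_um
  with_seed(derive_seed(spec$seed, "scene"), {
    cells <- matrix(NA_real_, nrow = n, ncol = 9)
    rad <- spec$diameter_um / 2
    acc_a <- matrix(0, 0, 3)  # accepted segment endpoints
    acc_b <- matrix(0, 0, 3)
    for (i in seq_len(n)) {
      len <- runif(1, spec$length_range_um[1], spec$length_range_um[2])
      ax <- .sample_axis(spec$orientation_model, spec$pitch_sigma_deg)
      hl <- len / 2 - rad               # axis segment half-length
      half_ext <- hl * abs(ax) + rad    # cell half-extent per dimension
      if (any(2 * half_ext > ext))
        stop(sprintf("cell %d (length %.2f um) does not fit the domain", i, len))
      placed <- FALSE
      for (attempt in seq_len(spec$max_placement_attempts)) {
        cx <- runif(1, half_ext[1], ext[1] - half_ext[1])
        cy <- runif(1, half_ext[2], ext[2] - half_ext[2])
        cz <- .sample_cell_z(spec, half_ext[3], ext[3])
        ctr <- c(cx, cy, cz)
        if (spec$overlap_policy == "reject" && nrow(acc_a) > 0) {
          d <- .segment_distances(ctr - hl * ax, ctr + hl * ax, acc_a, acc_b)
          if (any(d < rad + cells[seq_len(nrow(acc_a)), 6] / 2 +
                    spec$min_gap_um)) next
        }
        cells[i, ] <- c(ctr, 0, len, spec$diameter_um, ax)
        acc_a <- rbind(acc_a, ctr - hl * ax)
        acc_b <- rbind(acc_b, ctr + hl * ax)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "placement of cell %d failed after %d attempts; domain too crowded",
          i, spec$max_placement_attempts))
    }
    out <- data.frame(
      id = seq_len(n),
      x_um = cells[, 1], y_um = cells[, 2], z_um = cells[, 3],
      length_um = cells[, 5], diameter_um = cells[, 6],
      axis_x = cells[, 7], axis_y = cells[, 8], axis_z = cells[, 9],
      reflectivity = rep(spec$reflectivity, n))
    attr(out, "spec") <- spec
    class(out) <- c("cell_set", "data.frame")
    out
  })
}

# Centroid z respecting the orientation model; whole cell inside [0, Lz].
.sample_cell_z <- function(spec, half_ext_z, lz) {
  lo <- half_ext_z
  hi <- lz - half_ext_z
  if (spec$orientation_model == "isotropic")
    return(runif(1, lo, hi))
  sp <- spec$layer_spacing_um
  k_lo <- ceiling(lo / sp)
  k_hi <- floor(hi / sp)
  if (k_hi < k_lo) return(runif(1, lo, hi))  # too steep for any layer: free z
  k <- if (k_hi == k_lo) k_lo else sample(k_lo:k_hi, 1)
  jitter <- runif(1, -0.1, 0.1) * sp
  clamp(k * sp + jitter, lo, hi)
}

#' Pitch angles of a cell set
#'
#' @param cells A `cell_set` data frame (or any data frame with
#'   `axis_x/axis_y/axis_z` columns).
#' @return Pitch angles in degrees, `arcsin(|axis_z|)`, in `[0, 90]`.
#' @export
cell_pitches <- function(cells) {
  nrm <- sqrt(cells$axis_x^2 + cells$axis_y^2 + cells$axis_z^2)
  asin(abs(cells$axis_z) / nrm) * 180 / pi
}
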