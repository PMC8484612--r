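#' Pitch angle of a cell axis
#'
#' The pitching angle between a cell's long axis and the horizontal
#' (interface) plane: `arcsin(|axis_z|)`, in degrees, range `[0, 90]`.
#' Invariant under sign flips of the axis, which is physically
#' meaningless for a cell.
#'
#' @param axis Numeric length-3 vector (need not be normalized, but must
#'   be nonzero).
#' @return Angle in degrees.
#' @examples
#' pitch_angle(c(1, 0, 0))         # 0
#' pitch_angle(c(0, 0, 1))         # 90
#' pitch_angle(c(1, 0, 1))         # 45
#' @export
pitch_angle <- function(axis) {
  stopifnot(is.numeric(axis), length(axis) == 3L)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis must be a nonzero vector")
  asin(abs(axis[3]) / nrm) * 180 / pi
}

#' Principal axis of a voxel component from second moments
#'
#' Eigen-decomposition of the covariance of the component's physical
#' voxel-centre coordinates; the principal axis is the leading
#' eigenvector, sign-normalized to `axis_z >= 0` (ties broken to
#' `axis_x > 0`, then `axis_y > 0`). Components with fewer than 4 voxels
#' or with (numerically) coplanar voxels are flagged degenerate.
#'
#' @param coords_um Numeric `n x 3` matrix of `(x, y, z)` voxel-centre
#'   coordinates in micrometres.
#' @return List with `axis` (unit 3-vector), `eigenvalues`
#'   (`lambda1 >= lambda2 >= lambda3`, um^2) and `degenerate` flag.
#' @export
principal_axis <- function(coords_um) {
  coords_um <- as.matrix(coords_um)
  stopifnot(ncol(coords_um) == 3L)
  n <- nrow(coords_um)
  if (n < 4L)
    return(list(axis = c(NA_real_, NA_real_, NA_real_),
                eigenvalues = rep(NA_real_, 3), degenerate = TRUE))
  ev <- eigen(cov(coords_um), symmetric = TRUE)
  vals <- ev$values
  axis <- ev$vectors[, 1]
  if (axis[3] < 0) axis <- -axis
  if (abs(axis[3]) < 1e-9) {
    if (axis[1] < 0) axis <- -axis
    if (abs(axis[1]) < 1e-9 && axis[2] < 0) axis <- -axis
  }
  degenerate <- vals[3] <= 1e-9 * max(vals[1], 1e-12)
  list(axis = axis, eigenvalues = vals, degenerate = degenerate)
}

#' Measure every labeled cell in a segmentation
#'
#' One row per label: centroid (um, interface-anchored z), physical
#' volume, principal axis, eigenvalues-derived elongation
#' `sqrt(lambda1/lambda2)`, pitch angle, and a length estimate
#' `4 * sqrt(lambda1)`. Cells with `elongation < iso_cutoff` are flagged
#' isotropic and, like degenerate components, get `NA` pitch so they drop
#' out of angle statistics (they still count for volume and occupancy).
#'
#' @param labels A `label_volume`.
#' @param iso_cutoff Elongation below which a component is considered
#'   orientation-less (default 1.2).
#' @return Data frame with columns `label, x_um, y_um, z_um, volume_um3,
#'   axis_x, axis_y, axis_z, elongation, pitch_deg, length_um_est,
#'   flag_isotropic, flag_degenerate`.
#' @export
measure_cells <- function(labels, iso_cutoff = 1.2) {
  d <- dim(labels$data)
  vs <- labels$voxel_size
  idx <- which(labels$data > 0L)
  empty <- data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), volume_um3 = numeric(0),
                      axis_x = numeric(0), axis_y = numeric(0),
                      axis_z = numeric(0), elongation = numeric(0),
                      pitch_deg = numeric(0), length_um_est = numeric(0),
                      flag_isotropic = logical(0), flag_degenerate = logical(0))
  if (!length(idx)) return(empty)
  li <- labels$data[idx]
  ai <- arrayInd(idx, d)
  xyz <- cbind((ai[, 2] - 0.5) * vs[2],
               (ai[, 1] - 0.5) * vs[1],
               (ai[, 3] - labels$z_origin) * vs[3])
  voxel_vol <- prod(vs)
  groups <- split(seq_along(li), li)
  rows <- lapply(names(groups), function(g) {
    pts <- xyz[groups[[g]], , drop = FALSE]
    pa <- principal_axis(pts)
    elong <- if (pa$degenerate) NA_real_
             else sqrt(pa$eigenvalues[1] / max(pa$eigenvalues[2], 1e-12))
    iso <- !pa$degenerate && elong < iso_cutoff
    pitch <- if (pa$degenerate || iso) NA_real_ else pitch_angle(pa$axis)
    data.frame(label = as.integer(g),
               x_um = mean(pts[, 1]), y_um = mean(pts[, 2]),
               z_um = mean(pts[, 3]),
               volume_um3 = nrow(pts) * voxel_vol,
               axis_x = pa$axis[1], axis_y = pa$axis[2], axis_z = pa$axis[3],
               elongation = elong, pitch_deg = pitch,
               length_um_est = if (pa$degenerate) NA_real_
                               else 4 * sqrt(pa$eigenvalues[1]),
               flag_isotropic = iso, flag_degenerate = pa$degenerate)
  })
  out <- do.call(rbind, rows)
  out[order(out$label), , drop = FALSE]
}

#' Summary statistics of a pitch-angle population
#'
#' @param pitches_deg Pitch angles in degrees (`NA`s, e.g. isotropic or
#'   degenerate cells, are dropped).
#' @param thresholds_deg For each threshold, the fraction of cells with
#'   pitch strictly below it is reported.
#' @return List with `n`, `mean_deg` and `fraction_below` (named by
#'   threshold); an empty population reports `n = 0` and `NA` statistics.
#' @export
angle_summary <- function(pitches_deg, thresholds_deg = c(30, 45)) {
  p <- pitches_deg[!is.na(pitches_deg)]
  if (length(p) && (any(p < 0) || any(p > 90)))
    stop("pitch angles must lie in [0, 90] degrees")
  frac <- if (length(p)) vapply(thresholds_deg, function(t) mean(p < t), 0)
          else rep(NA_real_, length(thresholds_deg))
  names(frac) <- paste0("lt_", thresholds_deg)
  list(n = length(p),
       mean_deg = if (length(p)) mean(p) else NA_real_,
       fraction_below = frac)
}

# Resolve a region-of-interest argument to a logical (ny, nx) mask.
.as_roi_mask <- function(roi, labels) {
  d <- dim(labels$data)
  if (is.null(roi)) return(colony_roi(labels))
  if (is.logical(roi) && is.matrix(roi)) {
    if (!all(dim(roi) == d[1:2]))
      stop("roi mask dimensions must match the volume's (ny, nx)")
    if (!any(roi)) stop("roi is empty")
    return(roi)
  }
  if (is.list(roi) && !is.null(roi$x_um) && !is.null(roi$y_um)) {
    vs <- labels$voxel_size
    xs <- (seq_len(d[2]) - 0.5) * vs[2]
    ys <- (seq_len(d[1]) - 0.5) * vs[1]
    m <- outer(ys >= roi$y_um[1] & ys <= roi$y_um[2],
               xs >= roi$x_um[1] & xs <= roi$x_um[2], "&")
    if (!any(m)) stop("roi rectangle contains no voxel centres")
    return(m)
  }
  stop("roi must be NULL, a logical mask, or list(x_um=, y_um=)")
}

#' Default microcolony region of interest
#'
#' Reproducible stand-in for a hand-drawn microcolony outline: the
#' axis-aligned bounding rectangle of all labeled voxels projected to the
#' x,y plane, dilated by `dilate_um` (about one cell diameter) on every
#' side. With no labeled voxels the whole field is returned.
#'
#' @param labels A `label_volume`.
#' @param dilate_um Dilation margin in micrometres.
#' @return Logical `(ny, nx)` mask.
#' @export
colony_roi <- function(labels, dilate_um = 0.8) {
  d <- dim(labels$data)
  proj <- apply(labels$data > 0L, c(1, 2), any)
  if (!any(proj)) return(matrix(TRUE, d[1], d[2]))
  vs <- labels$voxel_size
  ry <- range(which(apply(proj, 1, any)))
  rx <- range(which(apply(proj, 2, any)))
  my <- as.integer(ceiling(dilate_um / vs[1]))
  mx <- as.integer(ceiling(dilate_um / vs[2]))
  mask <- matrix(FALSE, d[1], d[2])
  mask[max(1, ry[1] - my):min(d[1], ry[2] + my),
       max(1, rx[1] - mx):min(d[2], rx[2] + mx)] <- TRUE
  mask
}

#' Per-slice area occupation rate within a region of interest
#'
#' The local cell-density measure: for each z-slice, the fraction of ROI
#' voxels covered by labeled (cell) regions.
#'
#' @param labels A `label_volume` (segmentation or ground truth).
#' @param roi Region of interest (see [colony_roi()]; `NULL` uses the
#'   colony bounding box).
#' @return Data frame `(z_um, occupancy)`, z strictly increasing.
#' @export
occupancy_profile <- function(labels, roi = NULL) {
  mask <- .as_roi_mask(roi, labels)
  nz <- dim(labels$data)[3]
  occ <- vapply(seq_len(nz),
                function(k) mean(labels$data[, , k][mask] > 0L), 0)
  data.frame(z_um = (seq_len(nz) - labels$z_origin) * labels$voxel_size[3],
             occupancy = occ)
}

#' Reference slices of a colony: bottom, mid-height, top
#'
#' Operationalized as the 10th-percentile, median and 90th-percentile
#' occupied z-slices of the colony mask (slices with at least one labeled
#' voxel inside the ROI).
#'
#' @param labels A `label_volume`.
#' @param roi Region of interest (default colony bounding box).
#' @return Named integer vector `c(bottom=, mid=, top=)` of slice indices.
#' @export
colony_reference_slices <- function(labels, roi = NULL) {
  mask <- .as_roi_mask(roi, labels)
  nz <- dim(labels$data)[3]
  occupied <- which(vapply(seq_len(nz),
                           function(k) any(labels$data[, , k][mask] > 0L),
                           TRUE))
  if (!length(occupied)) stop("no labeled voxels inside the ROI")
  q <- quantile(occupied, c(0.1, 0.5, 0.9), type = 1)
  out <- as.integer(q)
  names(out) <- c("bottom", "mid", "top")
  out
}

#' Local cell-density heatmap
#'
#' Per slice, the field is partitioned into square tiles of `tile_um`
#' (default 2.4 um) and each tile reports its labeled-voxel fraction.
#' Partial edge tiles are normalized by their own voxel count, so the
#' voxel-count-weighted mean of all tiles equals the full-field slice
#' occupancy.
#'
#' @param labels A `label_volume`.
#' @param tile_um Tile edge length in micrometres.
#' @return List of class `density_heatmap`: `tiles` (3D array
#'   `(tile_y, tile_x, z)` of occupancies), `tile_voxels` (2D counts),
#'   `tile_um`, `z_um`.
#' @export
density_heatmap <- function(labels, tile_um = 2.4) {
  vs <- labels$voxel_size
  if (tile_um < max(vs[1:2]))
    stop("tile_um must be at least one voxel")
  d <- dim(labels$data)
  gy <- ceiling(((seq_len(d[1]) - 0.5) * vs[1]) / tile_um)
  gx <- ceiling(((seq_len(d[2]) - 0.5) * vs[2]) / tile_um)
  nty <- max(gy); ntx <- max(gx)
  counts <- as.matrix(table(factor(rep(gy, times = d[2]), levels = 1:nty),
                            factor(rep(gx, each = d[1]), levels = 1:ntx)))
  tiles <- array(0, dim = c(nty, ntx, d[3]))
  for (k in seq_len(d[3])) {
    m <- rowsum((labels$data[, , k] > 0L) + 0, gy, reorder = TRUE)
    m <- t(rowsum(t(m), gx, reorder = TRUE))
    tiles[, , k] <- m / counts
  }
  structure(list(tiles = tiles, tile_voxels = counts, tile_um = tile_um,
                 z_um = (seq_len(d[3]) - labels$z_origin) * vs[3]),
            class = "density_heatmap")
}

#' Axial mean-intensity profile of a stack
#'
#' Mean intensity per z-slice over the field of view, optionally excluding
#' a 2D region (e.g. a paint mark used for interface localization).
#'
#' @param stack A [zstack()].
#' @param exclusion Optional logical `(ny, nx)` matrix of voxels to
#'   exclude on every slice.
#' @return Data frame `(z_um, mean_intensity)`.
#' @export
axial_intensity_profile <- function(stack, exclusion = NULL) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$data)
  if (!is.null(exclusion)) {
    if (!is.logical(exclusion) || !all(dim(exclusion) == d[1:2]))
      stop("exclusion must be a logical (ny, nx) matrix matching the stack")
    if (all(exclusion)) stop("exclusion covers the full field")
    keep <- !exclusion
    prof <- apply(stack$data, 3, function(sl) mean(sl[keep]))
  } else {
    prof <- apply(stack$data, 3, mean)
  }
  data.frame(z_um = z_coords(stack), mean_intensity = prof)
}

#' Signal-to-background ratio on a slice above the interface
#'
#' Samples `n_regions` small square patches entirely inside cell regions
#' and `n_regions` patches entirely in the background of the slice at
#' `z = z_offset_um` (default +1 um, the convention when the interface
#' plane itself is saturated), and reports the ratio of the mean cell
#' patch intensity to the mean background patch intensity. Sampling is
#' without replacement and deterministic given `seed`.
#'
#' @param stack A [zstack()].
#' @param labels A `label_volume` on the same grid.
#' @param z_offset_um Offset above the interface, um.
#' @param n_regions Patches per class (default 20).
#' @param seed Integer seed for patch sampling.
#' @param patch_voxels Patch edge length in voxels (default 3).
#' @return List of class `sbr_result`: `cell_mean`, `background_mean`,
#'   `ratio`, `n_regions`, `z_offset_um`, `slice_index`.
#' @export
signal_background_ratio <- function(stack, labels, z_offset_um = 1,
                                    n_regions = 20L, seed = 1L,
                                    patch_voxels = 3L) {
  stopifnot(inherits(stack, "zstack"))
  if (!all(dim(stack$data) == dim(labels$data)))
    stop("stack and labels are on different grids")
  k <- z_index(stack, z_offset_um)
  sl <- stack$data[, , k]
  cellmask <- labels$data[, , k] > 0L
  half <- (patch_voxels - 1L) %/% 2L
  cell_ctr <- .patch_centres(cellmask, half, want = TRUE)
  bg_ctr <- .patch_centres(cellmask, half, want = FALSE)
  if (nrow(cell_ctr) < n_regions)
    stop(sprintf("only %d candidate cell patches on the slice (need %d)",
                 nrow(cell_ctr), n_regions))
  if (nrow(bg_ctr) < n_regions)
    stop(sprintf("only %d candidate background patches on the slice (need %d)",
                 nrow(bg_ctr), n_regions))
  with_seed(derive_seed(seed, "sbr"), {
    ci <- cell_ctr[sample(nrow(cell_ctr), n_regions), , drop = FALSE]
    bi <- bg_ctr[sample(nrow(bg_ctr), n_regions), , drop = FALSE]
    patch_mean <- function(ctr)
      mean(sl[(ctr[1] - half):(ctr[1] + half), (ctr[2] - half):(ctr[2] + half)])
    cm <- mean(apply(ci, 1, patch_mean))
    bm <- mean(apply(bi, 1, patch_mean))
    structure(list(cell_mean = cm, background_mean = bm, ratio = cm / bm,
                   n_regions = as.integer(n_regions),
                   z_offset_um = z_offset_um, slice_index = k),
              class = "sbr_result")
  })
}

# Centres whose full (2*half+1)^2 patch is entirely cell (want=TRUE) or
# entirely background (want=FALSE).
.patch_centres <- function(cellmask, half, want) {
  target <- if (want) cellmask else !cellmask
  ok <- target
  if (half > 0) {
    d <- dim(target)
    for (dy in -half:half) for (dx in -half:half) {
      if (dy == 0 && dx == 0) next
      sh <- matrix(FALSE, d[1], d[2])
      ys <- intersect(seq_len(d[1]), seq_len(d[1]) - dy)
      xs <- intersect(seq_len(d[2]), seq_len(d[2]) - dx)
      sh[ys, xs] <- target[ys + dy, xs + dx]
      ok <- ok & sh
    }
    # patches must not touch the border
    ok[c(seq_len(half), d[1] - seq_len(half) + 1L), ] <- FALSE
    ok[, c(seq_len(half), d[2] - seq_len(half) + 1L)] <- FALSE
  }
  which(ok, arr.ind = TRUE)
}

#' Fold improvement between two signal-to-background ratios
#'
#' @param sbr_with,sbr_without `sbr_result` objects or bare ratios; e.g.
#'   the SBR measured over an index-matched coating vs over bare glass.
#' @return `sbr_with / sbr_without` as a plain number.
#' @examples
#' sbr_fold_improvement(15.8, 1.8)   # ~8.8
#' @export
sbr_fold_improvement <- function(sbr_with, sbr_without) {
  r1 <- if (inherits(sbr_with, "sbr_result")) sbr_with$ratio else sbr_with
  r2 <- if (inherits(sbr_without, "sbr_result")) sbr_without$ratio else sbr_without
  if (r2 <= 0) stop("reference ratio must be positive")
  r1 / r2
}

#' @export
print.sbr_result <- function(x, ...) {
  cat(sprintf(
    "SBR at z = +%g um: cell %.1f / background %.1f a.u. -> ratio %.2f (n = %d per class)\n",
    x$z_offset_um, x$cell_mean, x$background_mean, x$ratio, x$n_regions))
  invisible(x)
}
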