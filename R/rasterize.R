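# Voxel grid shared by ground-truth label volumes and rendered stacks.
# Slice centres sit at z = (k - z_origin) * dz so one slice lies exactly on
# the interface plane; x/y voxel centres at (i - 0.5) * pitch.
.scene_grid <- function(spec) {
  vy <- spec$voxel_size_um[1]
  vx <- spec$voxel_size_um[2]
  vz <- spec$voxel_size_um[3]
  ny <- as.integer(round(spec$extent_um[2] / vy))
  nx <- as.integer(round(spec$extent_um[1] / vx))
  z_origin <- as.integer(ceiling(spec$z_margin_below_um / vz)) + 1L
  nz <- z_origin + as.integer(ceiling(spec$extent_um[3] / vz))
  list(ny = ny, nx = nx, nz = nz, z_origin = z_origin,
       voxel_size = c(vy, vx, vz))
}

#' Rasterize a cell population into a ground-truth label volume
#'
#' Voxels are labeled with a cell's id iff the voxel centre lies within
#' `diameter/2` of the cell's axis segment (the spherocylinder inclusion
#' test). When cells overlap (`overlap_policy = "allow"`), later cells
#' overwrite earlier ones.
#'
#' @param cells A `cell_set` from [sample_scene()].
#' @param spec The [scene_spec()]; defaults to the spec attached to
#'   `cells`.
#' @return An object of class `ground_truth`: list with `cells`, `labels`
#'   (a `label_volume`: integer `(y, x, z)` array with `voxel_size`,
#'   `z_origin`, `n_labels`) and `spec`.
#' @export
rasterize_cells <- function(cells, spec = attr(cells, "spec")) {
  if (is.null(spec)) stop("no scene_spec supplied or attached to cells")
  g <- .scene_grid(spec)
  lab <- array(0L, dim = c(g$ny, g$nx, g$nz))
  vy <- g$voxel_size[1]; vx <- g$voxel_size[2]; vz <- g$voxel_size[3]
  for (i in seq_len(nrow(cells))) {
    ctr <- c(cells$x_um[i], cells$y_um[i], cells$z_um[i])
    ax <- c(cells$axis_x[i], cells$axis_y[i], cells$axis_z[i])
    rad <- cells$diameter_um[i] / 2
    hl <- cells$length_um[i] / 2 - rad
    a <- ctr - hl * ax
    b <- ctr + hl * ax
    # bounding box in voxel indices
    ix <- .bbox_idx(min(a[1], b[1]) - rad, max(a[1], b[1]) + rad, vx, g$nx,
                    offset = 0.5)
    iy <- .bbox_idx(min(a[2], b[2]) - rad, max(a[2], b[2]) + rad, vy, g$ny,
                    offset = 0.5)
    iz <- .bbox_idx(min(a[3], b[3]) - rad, max(a[3], b[3]) + rad, vz, g$nz,
                    offset = 0, origin = g$z_origin)
    if (!length(ix) || !length(iy) || !length(iz)) next
    xs <- (ix - 0.5) * vx
    ys <- (iy - 0.5) * vy
    zs <- (iz - g$z_origin) * vz
    # squared distance of each voxel centre to the axis segment
    px <- rep(xs, each = length(iy))
    py <- rep(ys, times = length(ix))
    u <- b - a
    len2 <- sum(u * u)
    for (kk in seq_along(iz)) {
      rx <- px - a[1]; ry <- py - a[2]; rz <- zs[kk] - a[3]
      tt <- if (len2 > 1e-12)
        clamp((rx * u[1] + ry * u[2] + rz * u[3]) / len2, 0, 1) else 0
      d2 <- (rx - tt * u[1])^2 + (ry - tt * u[2])^2 + (rz - tt * u[3])^2
      inside <- d2 <= rad^2
      if (any(inside)) {
        sl <- lab[iy, ix, iz[kk]]
        sl[inside] <- cells$id[i]
        lab[iy, ix, iz[kk]] <- sl
      }
    }
  }
  labels <- structure(list(data = lab, voxel_size = g$voxel_size,
                           z_origin = g$z_origin, n_labels = max(lab)),
                      class = "label_volume")
  structure(list(cells = cells, labels = labels, spec = spec),
            class = "ground_truth")
}

# Voxel indices whose centres can fall in [lo, hi] um. For x/y the centre
# of index i is (i - offset) * pitch; for z it is (i - origin) * pitch.
.bbox_idx <- function(lo, hi, pitch, n, offset = 0.5, origin = 0) {
  if (offset > 0) {
    i0 <- floor(lo / pitch + offset)
    i1 <- ceiling(hi / pitch + offset)
  } else {
    i0 <- floor(lo / pitch + origin)
    i1 <- ceiling(hi / pitch + origin)
  }
  lo_i <- max(1L, as.integer(i0))
  hi_i <- min(n, as.integer(i1))
  if (hi_i < lo_i) integer(0) else lo_i:hi_i
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cells, label volume %s, %d labels\n",
              nrow(x$cells),
              paste(dim(x$labels$data), collapse = " x "),
              x$labels$n_labels))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels (y,x,z), %d labels, voxel %s um\n",
              paste(dim(x$data), collapse = " x "), x$n_labels,
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}
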