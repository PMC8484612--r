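#' Reflection z-stack volume
#'
#' The pipeline's universal input: a 3D intensity volume with physical
#' voxel size and a z origin anchored at the solid--liquid interface.
#' Voxels are stored as a `(y, x, z)` array; slice `k` is centred at
#' `z = (k - z_origin) * dz` micrometres, so slice `z_origin` lies exactly
#' on the interface plane and slices below it image into the solid.
#'
#' @param data Numeric 3D array, dimensions `(ny, nx, nz)`, intensities in
#'   arbitrary units (a.u.), all `>= 0`.
#' @param voxel_size Numeric length-3 vector `c(dy, dx, dz)` in micrometres.
#' @param z_origin Integer slice index (1-based) of the interface plane.
#' @return An object of class `zstack`.
#' @export
zstack <- function(data, voxel_size, z_origin) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (y, x, z)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths c(dy, dx, dz) in um")
  z_origin <- as.integer(z_origin)
  if (z_origin < 1L || z_origin > dim(data)[3])
    stop("z_origin must index a slice of the stack")
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(list(data = data, voxel_size = voxel_size, z_origin = z_origin),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("zstack: %d x %d x %d voxels (y,x,z), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  interface plane at slice %d; z range [%.2f, %.2f] um\n",
              x$z_origin, min(z_coords(x)), max(z_coords(x))))
  cat(sprintf("  intensity range [%.4g, %.4g] a.u.\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical z coordinate of each slice
#'
#' @param stack A [zstack()] (or a label volume sharing its grid fields).
#' @return Numeric vector of slice-centre z positions in micrometres,
#'   0 at the solid--liquid interface.
#' @export
z_coords <- function(stack) {
  (seq_len(dim(stack$data)[3]) - stack$z_origin) * stack$voxel_size[3]
}

#' Slice index closest to a physical z position
#'
#' @param stack A [zstack()].
#' @param z_um Physical z in micrometres from the interface.
#' @return 1-based slice index.
#' @export
z_index <- function(stack, z_um) {
  k <- stack$z_origin + as.integer(round(z_um / stack$voxel_size[3]))
  if (k < 1L || k > dim(stack$data)[3])
    stop(sprintf("z = %g um is outside the stack (slices span %.2f..%.2f um)",
                 z_um, min(z_coords(stack)), max(z_coords(stack))))
  k
}

# 16-bit multipage TIFF + JSON sidecar. tiff stores samples in [0,1]; we
# scale by 65535 so integer a.u. up to 65535 survive the round trip to
# within the 16-bit quantum.
.sidecar_path <- function(path) paste0(path, ".json")

#' Write a z-stack as multi-page TIFF with JSON sidecar metadata
#'
#' Each slice becomes one 16-bit TIFF page (intensities quantized to
#' ~1 a.u.); voxel size, z origin and units go to `<path>.json`.
#'
#' @param stack A [zstack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  if (max(stack$data) > 65535)
    stop("intensities exceed the 16-bit range of the TIFF container")
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(k) stack$data[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = stack$voxel_size, z_origin = stack$z_origin,
         axis_order = "y,x,z", intensity_units = "a.u.",
         intensity_scale = 65535),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a z-stack written by [write_stack()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A [zstack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- .sidecar_path(path)
  if (!file.exists(side))
    stop("missing metadata sidecar (voxel size, z origin): ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (key in c("voxel_size_um", "z_origin"))
    if (is.null(meta[[key]])) stop("sidecar missing key '", key, "': ", side)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  scale <- if (is.null(meta$intensity_scale)) 65535 else meta$intensity_scale
  zstack(round(arr * scale, 6), meta$voxel_size_um, meta$z_origin)
}

#' Write an integer label volume as multi-page TIFF
#'
#' @param labels A label volume (list with `data`, `voxel_size`,
#'   `z_origin`), labels 0..K with K < 65536.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (max(labels$data) > 65535) stop("more than 65535 labels")
  pages <- lapply(seq_len(dim(labels$data)[3]),
                  function(k) labels$data[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = labels$voxel_size, z_origin = labels$z_origin,
         axis_order = "y,x,z", n_labels = max(labels$data)),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#'
#' @param path TIFF path.
#' @return A label volume: list with integer `data`, `voxel_size`,
#'   `z_origin`, `n_labels`.
#' @export
read_labels <- function(path) {
  st <- read_stack(path)
  data <- array(as.integer(round(st$data)), dim = dim(st$data))
  structure(list(data = data, voxel_size = st$voxel_size,
                 z_origin = st$z_origin, n_labels = max(data)),
            class = "label_volume")
}

#' Maximum-intensity projection of a stack along z
#'
#' @param stack A [zstack()].
#' @param z_min_um Ignore slices below this z (defaults to just above the
#'   interface so a saturated glass plane does not dominate).
#' @return A `(ny, nx)` intensity matrix.
#' @export
max_projection <- function(stack, z_min_um = 0) {
  keep <- z_coords(stack) >= z_min_um
  if (!any(keep)) stop("no slices at or above z = ", z_min_um, " um")
  apply(stack$data[, , keep, drop = FALSE], c(1, 2), max)
}
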