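#' Parameters of the single-cell segmentation pipeline
#'
#' The pipeline is: (optionally) drop slices below `exclude_slices_below_um`
#' (forced to background and excluded from threshold statistics; this keeps
#' a saturated glass plane from swallowing surface cells), global
#' threshold (Otsu on retained voxels, or a fixed value; an Otsu split
#' whose foreground does not exceed the background by at least 3
#' background standard deviations is treated as no foreground, so
#' baseline+noise-only stacks yield zero labels), binary opening,
#' 3D connected components, minimum-volume filter, deterministic
#' relabeling.
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold a.u.; required iff `threshold_method = "fixed"`.
#' @param min_volume_um3 Discard components smaller than this physical
#'   volume.
#' @param opening_radius Binary opening radius in voxels (0 disables).
#' @param connectivity 6, 18 or 26 (3D neighbourhood).
#' @param exclude_slices_below_um Slices with z below this (um from the
#'   interface) are excluded; default 1 um, matching the convention of
#'   analysing from +1 um when the interface plane itself is saturated.
#'   Use 0 for index-matched stacks, where the interface is dark.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_volume_um3 = 0.5,
                                opening_radius = 1L,
                                connectivity = 26L,
                                exclude_slices_below_um = 1) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || !is.numeric(fixed_threshold)))
    stop("fixed_threshold required when threshold_method = 'fixed'")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (min_volume_um3 < 0) stop("min_volume_um3 must be >= 0")
  if (opening_radius < 0) stop("opening_radius must be >= 0")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_volume_um3 = min_volume_um3,
                 opening_radius = as.integer(opening_radius),
                 connectivity = as.integer(connectivity),
                 exclude_slices_below_um = exclude_slices_below_um),
            class = "segmentation_params")
}

#' Otsu's threshold of an intensity sample
#'
#' Maximizes between-class variance over a histogram of `n_bins` equal
#' bins. Returns a threshold value; voxels strictly above it are
#' foreground. For a constant input the common value is returned (nothing
#' is foreground).
#'
#' @param v Numeric vector of intensities.
#' @param n_bins Histogram resolution.
#' @return Threshold in the units of `v`.
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values")
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) return(lo)
  h <- tabulate(pmin(n_bins, 1L + as.integer((v - lo) / (hi - lo) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centres <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  mu <- cumsum(p * centres)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  lo + k * (hi - lo) / n_bins   # upper edge of the argmax bin
}

#' Locate the solid--liquid interface plane in a z-stack
#'
#' The interface is the slice where the mean intensity (inside
#' `mark_region` if given, e.g. a reflective paint mark, otherwise the
#' whole field) is maximal; if saturation produces a plateau of maximal
#' slices, the plateau centre is taken. If the maximum slice mean is less than twice
#' the median slice mean there is no detectable reflection peak (the
#' signature of an index-matched interface) and the stack's declared
#' `z_origin` is returned with `no_peak = TRUE`.
#'
#' @param stack A [zstack()].
#' @param mark_region Optional `(ny, nx)` logical matrix selecting the
#'   region whose axial profile is used.
#' @return List with `index` (slice), `z_um`, `no_peak` and the slice-mean
#'   `profile`.
#' @export
locate_interface <- function(stack, mark_region = NULL) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$data)
  if (!is.null(mark_region)) {
    if (!is.logical(mark_region) || !all(dim(mark_region) == d[1:2]))
      stop("mark_region must be a logical (ny, nx) matrix matching the stack")
    if (!any(mark_region)) stop("mark_region is empty")
    prof <- apply(stack$data, 3, function(sl) mean(sl[mark_region]))
  } else {
    prof <- apply(stack$data, 3, mean)
  }
  # a saturated interface yields a plateau of maximal slices; take its centre
  plateau <- which(prof >= max(prof) * (1 - 1e-9))
  k <- as.integer(round(median(plateau)))
  no_peak <- max(prof) < 2 * median(prof)
  if (no_peak) k <- stack$z_origin
  list(index = as.integer(k), z_um = (k - stack$z_origin) * stack$voxel_size[3],
       no_peak = no_peak, profile = prof)
}

#' Mean background intensity on a slice above the interface
#'
#' Evaluated at `z = z_offset_um` above the interface (conventionally
#' +1 um, clear of any saturated interface plane). Non-cell
#' voxels are those strictly below a threshold: voxels outside `labels`
#' if a segmentation is supplied, otherwise below `threshold` (Otsu of the
#' slice when `NULL`). If the below-threshold class is empty (constant
#' slice) the whole slice is used.
#'
#' @param stack A [zstack()].
#' @param z_offset_um Offset above the interface, um.
#' @param labels Optional `label_volume` on the same grid.
#' @param threshold Optional fixed threshold, a.u.
#' @return Mean background intensity, a.u.
#' @export
estimate_background <- function(stack, z_offset_um = 1, labels = NULL,
                                threshold = NULL) {
  stopifnot(inherits(stack, "zstack"))
  k <- z_index(stack, z_offset_um)
  sl <- stack$data[, , k]
  if (!is.null(labels)) {
    bg <- sl[labels$data[, , k] == 0]
  } else {
    thr <- threshold %||% otsu_threshold(as.numeric(sl))
    bg <- sl[sl < thr]
  }
  if (!length(bg)) bg <- sl
  mean(bg)
}

#' Segment single cells in a reflection z-stack
#'
#' See [segmentation_params()] for the pipeline. Components are relabeled
#' `1..K` deterministically by their (min z, min y, min x) voxel. An
#' all-background result (`K = 0`) is valid. Touching cells merge into one
#' component: the pipeline reports merges, it does not split them.
#'
#' @param stack A [zstack()].
#' @param params A [segmentation_params()].
#' @return A `label_volume` (integer `(y, x, z)` array, `voxel_size`,
#'   `z_origin`, `n_labels`, plus the `threshold` used and `params`).
#' @export
segment_cells <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "zstack"), inherits(params, "segmentation_params"))
  zs <- z_coords(stack)
  retain <- zs >= params$exclude_slices_below_um
  if (!any(retain)) stop("exclude_slices_below_um removes every slice")
  thr <- if (params$threshold_method == "fixed") params$fixed_threshold
         else otsu_threshold(as.numeric(stack$data[, , retain]))
  mask <- stack$data > thr
  mask[, , !retain] <- FALSE
  if (params$threshold_method == "otsu" && any(mask)) {
    # contrast guard: on a baseline+noise-only stack Otsu bisects the noise
    # distribution; demand the foreground exceed the background by at least
    # 3 background SDs before accepting any foreground at all
    v <- stack$data[, , retain]
    fg <- v > thr
    if (any(fg) && any(!fg) &&
        mean(v[fg]) - mean(v[!fg]) < 3 * stats::sd(v[!fg]))
      mask[] <- FALSE
  }
  if (params$opening_radius > 0)
    mask <- .binary_open3d(mask, params$opening_radius)
  lab <- .cc_label3d(mask, params$connectivity)
  voxel_vol <- prod(stack$voxel_size)
  if (max(lab) > 0) {
    counts <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(counts * voxel_vol >= params$min_volume_um3)
    lab <- .relabel_sorted(lab, keep)
  }
  structure(list(data = lab, voxel_size = stack$voxel_size,
                 z_origin = stack$z_origin, n_labels = max(lab),
                 threshold = thr, params = params),
            class = "label_volume")
}

# Keep only `keep` labels and renumber 1..K by (min z, min y, min x).
.relabel_sorted <- function(lab, keep) {
  d <- dim(lab)
  idx <- which(lab > 0L)
  if (!length(idx) || !length(keep)) {
    lab[] <- 0L
    return(lab)
  }
  li <- lab[idx]
  sel <- li %in% keep
  idx <- idx[sel]; li <- li[sel]
  ai <- arrayInd(idx, d)
  minz <- tapply(ai[, 3], li, min)
  miny <- tapply(ai[, 1], li, min)
  minx <- tapply(ai[, 2], li, min)
  ord <- order(minz, miny, minx)
  old_ids <- as.integer(names(minz))[ord]
  remap <- integer(max(old_ids))
  remap[old_ids] <- seq_along(old_ids)
  out <- array(0L, dim = d)
  out[idx] <- remap[li]
  out
}
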