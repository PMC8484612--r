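#' Imaging model for synthetic reflection stacks
#'
#' Parameters of the confocal-reflection image formation emulated by
#' [render_stack()]: anisotropic Gaussian PSF, interface reflection term,
#' intensity gains, detector baseline, shot/read noise and saturation.
#' Default gains place the simulator at a plausible 12-bit operating
#' point: detector baseline ~86 a.u., cell interiors ~1370 a.u. (so the
#' cell-to-background ratio over an index-matched surface is ~16), and a
#' glass--water interface peak that saturates the detector.
#'
#' @param psf_lateral_fwhm_um,psf_axial_fwhm_um Gaussian PSF FWHM (um).
#' @param reflectance_to_intensity_gain a.u. of interface peak amplitude
#'   per unit Fresnel reflectance.
#' @param cell_intensity_scale a.u. added inside a cell of reflectivity 1.
#' @param baseline_au Constant detector offset, a.u.
#' @param poisson_gain Photons per a.u.; 0 disables shot noise.
#' @param read_noise_sd a.u.; 0 disables read noise.
#' @param saturation_level a.u.; intensities are clipped here.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(psf_lateral_fwhm_um = 0.23,
                         psf_axial_fwhm_um = 0.5,
                         reflectance_to_intensity_gain = 2e6,
                         cell_intensity_scale = 1280,
                         baseline_au = 86.4,
                         poisson_gain = 2,
                         read_noise_sd = 2,
                         saturation_level = 4095,
                         seed = 1L) {
  if (psf_lateral_fwhm_um <= 0 || psf_axial_fwhm_um <= 0)
    stop("PSF FWHMs must be positive")
  if (baseline_au < 0) stop("baseline_au must be >= 0")
  if (saturation_level <= baseline_au)
    stop("saturation_level must exceed baseline_au")
  if (poisson_gain < 0 || read_noise_sd < 0)
    stop("noise parameters must be >= 0")
  structure(list(psf_lateral_fwhm_um = psf_lateral_fwhm_um,
                 psf_axial_fwhm_um = psf_axial_fwhm_um,
                 reflectance_to_intensity_gain = reflectance_to_intensity_gain,
                 cell_intensity_scale = cell_intensity_scale,
                 baseline_au = baseline_au,
                 poisson_gain = poisson_gain,
                 read_noise_sd = read_noise_sd,
                 saturation_level = saturation_level,
                 seed = as.integer(seed)),
            class = "imaging_spec")
}

#' Noise-free variant of an imaging spec
#'
#' @param imaging An [imaging_spec()].
#' @return The same spec with shot and read noise disabled.
#' @export
noise_free <- function(imaging) {
  imaging$poisson_gain <- 0
  imaging$read_noise_sd <- 0
  imaging
}

# Separable Gaussian blur along one array dimension: shift-and-add with a
# kernel truncated at 4 sigma, renormalized near the borders so constant
# fields are preserved exactly.
.blur_along <- function(arr, dim_i, sigma_vox) {
  if (sigma_vox < 1e-3) return(arr)
  n <- dim(arr)[dim_i]
  hw <- min(n - 1L, as.integer(ceiling(4 * sigma_vox)))
  w <- exp(-((-hw):hw)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  d <- dim(arr)
  perm <- c(dim_i, setdiff(1:3, dim_i))
  a <- matrix(aperm(arr, perm), nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(a))
  norm <- numeric(n)
  for (k in (-hw):hw) {
    dst <- max(1L, 1L - k):min(n, n - k)
    out[dst, ] <- out[dst, ] + w[k + hw + 1L] * a[dst + k, , drop = FALSE]
    norm[dst] <- norm[dst] + w[k + hw + 1L]
  }
  out <- out / norm
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Blur a volume with an anisotropic Gaussian PSF
#'
#' @param arr `(y, x, z)` array.
#' @param lateral_fwhm_um,axial_fwhm_um Gaussian FWHM in micrometres.
#' @param voxel_size `c(dy, dx, dz)` in micrometres.
#' @return Blurred array of the same shape.
#' @export
blur_psf <- function(arr, lateral_fwhm_um, axial_fwhm_um, voxel_size) {
  s <- c(lateral_fwhm_um, lateral_fwhm_um, axial_fwhm_um) / 2.354820045
  arr <- .blur_along(arr, 1L, s[1] / voxel_size[1])
  arr <- .blur_along(arr, 2L, s[2] / voxel_size[2])
  .blur_along(arr, 3L, s[3] / voxel_size[3])
}

#' Render a ground-truth scene into a reflection z-stack
#'
#' Image formation: `baseline + cell term + interface term`, blurred by
#' an anisotropic Gaussian PSF, then Poisson shot noise and Gaussian read
#' noise (each optional), clipped to `[0, saturation_level]`. The
#' interface term is an x,y-uniform axial Gaussian centred on the
#' interface plane with FWHM equal to the axial PSF FWHM and amplitude
#' `fresnel_reflectance(interface) * reflectance_to_intensity_gain` — the
#' background reflection of an index-mismatched solid--liquid interface.
#' With an index-matched interface the amplitude is ~0 and the rendered
#' background reduces to the detector baseline.
#'
#' @param truth A `ground_truth` from [rasterize_cells()].
#' @param imaging An [imaging_spec()].
#' @param interface An [ri_interface()] (e.g. glass/water 1.5255/1.333, or
#'   IMM/water 1.33/1.333).
#' @return A [zstack()] on the same grid as `truth$labels`.
#' @export
render_stack <- function(truth, imaging, interface) {
  stopifnot(inherits(truth, "ground_truth"), inherits(imaging, "imaging_spec"),
            inherits(interface, "ri_interface"))
  lab <- truth$labels
  d <- dim(lab$data)
  refl <- truth$cells$reflectivity[match(lab$data, truth$cells$id)]
  refl[is.na(refl)] <- 0
  field <- array(imaging$cell_intensity_scale * refl, dim = d)
  zc <- (seq_len(d[3]) - lab$z_origin) * lab$voxel_size[3]
  amp <- fresnel_reflectance(interface) * imaging$reflectance_to_intensity_gain
  axial <- amp * exp(-4 * log(2) * zc^2 / imaging$psf_axial_fwhm_um^2)
  field <- sweep(field, 3, axial, "+")
  field <- blur_psf(field, imaging$psf_lateral_fwhm_um,
                    imaging$psf_axial_fwhm_um, lab$voxel_size)
  field <- field + imaging$baseline_au
  if (imaging$poisson_gain > 0 || imaging$read_noise_sd > 0) {
    field <- with_seed(derive_seed(imaging$seed, "noise"), {
      v <- as.numeric(field)
      if (imaging$poisson_gain > 0)
        v <- rpois(length(v), v * imaging$poisson_gain) / imaging$poisson_gain
      if (imaging$read_noise_sd > 0)
        v <- v + rnorm(length(v), 0, imaging$read_noise_sd)
      array(v, dim = d)
    })
  }
  field <- clamp(field, 0, imaging$saturation_level)
  zstack(field, lab$voxel_size, lab$z_origin)
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper: sample a scene, rasterize it, render it.
#'
#' @param spec A [scene_spec()].
#' @param imaging An [imaging_spec()]; its seed is taken from the scene
#'   seed unless set explicitly.
#' @param interface An [ri_interface()]; default index-matched IMM/water.
#' @return List with `truth` (ground truth) and `stack` ([zstack()]).
#' @export
simulate_stack <- function(spec, imaging = imaging_spec(seed = spec$seed),
                           interface = ri_interface(1.33, 1.333)) {
  cells <- sample_scene(spec)
  truth <- rasterize_cells(cells, spec)
  list(truth = truth, stack = render_stack(truth, imaging, interface))
}
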