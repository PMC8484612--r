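#' Optical configuration of a confocal reflection microscope
#'
#' Bundles the parameters that set the resolution of a confocal system:
#' excitation wavelength, objective numerical aperture, immersion-medium
#' refractive index and pinhole diameter in Airy units.
#'
#' @param wavelength_nm Laser wavelength in nanometres (e.g. 561).
#' @param numerical_aperture Objective NA; must satisfy
#'   `0 < numerical_aperture <= immersion_ri`.
#' @param immersion_ri Refractive index of the immersion medium
#'   (1.0 dry, 1.333 water, ~1.515 oil).
#' @param pinhole_au Confocal pinhole diameter as a multiple of the Airy
#'   unit (dimensionless, > 0).
#' @return An object of class `optical_config`.
#' @examples
#' optical_config(561, 1.4, 1.515, 1.2)
#' @export
optical_config <- function(wavelength_nm, numerical_aperture, immersion_ri,
                           pinhole_au = 1.2) {
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1L,
            is.numeric(numerical_aperture), length(numerical_aperture) == 1L,
            is.numeric(immersion_ri), length(immersion_ri) == 1L,
            is.numeric(pinhole_au), length(pinhole_au) == 1L)
  if (wavelength_nm <= 0) stop("wavelength_nm must be positive")
  if (numerical_aperture <= 0) stop("numerical_aperture must be positive")
  if (numerical_aperture > immersion_ri)
    stop("numerical_aperture must not exceed immersion_ri (evanescent regime)")
  if (pinhole_au <= 0) stop("pinhole_au must be positive")
  structure(list(wavelength_nm = wavelength_nm,
                 numerical_aperture = numerical_aperture,
                 immersion_ri = immersion_ri,
                 pinhole_au = pinhole_au),
            class = "optical_config")
}

#' Index-matching material (IMM) layer
#'
#' @param refractive_index Refractive index of the layer (>= 1).
#' @param thickness_um Layer thickness in micrometres (>= 0; 0 means no
#'   layer).
#' @return An object of class `imm_layer`.
#' @examples
#' imm_layer(1.33, 20)
#' @export
imm_layer <- function(refractive_index, thickness_um) {
  stopifnot(is.numeric(refractive_index), is.numeric(thickness_um))
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  if (thickness_um < 0) stop("thickness_um must be >= 0")
  structure(list(refractive_index = refractive_index,
                 thickness_um = thickness_um),
            class = "imm_layer")
}

#' Planar refractive-index interface
#'
#' @param ri_incident Refractive index on the incidence side (> 0).
#' @param ri_transmitted Refractive index on the transmission side (> 0).
#' @return An object of class `ri_interface`.
#' @examples
#' ri_interface(1.5255, 1.333)   # glass / water
#' @export
ri_interface <- function(ri_incident, ri_transmitted) {
  if (!is.numeric(ri_incident) || !is.numeric(ri_transmitted) ||
      ri_incident <= 0 || ri_transmitted <= 0)
    stop("refractive indices must be positive numbers")
  structure(list(ri_incident = ri_incident, ri_transmitted = ri_transmitted),
            class = "ri_interface")
}

#' Airy unit diameter in object space
#'
#' The Airy disk diameter `1.22 * lambda / NA`, the unit in which confocal
#' pinholes are sized.
#'
#' @param wavelength_nm Wavelength in nm.
#' @param numerical_aperture Objective NA.
#' @return Diameter in micrometres.
#' @examples
#' airy_unit_diameter(561, 1.4)
#' @export
airy_unit_diameter <- function(wavelength_nm, numerical_aperture) {
  if (wavelength_nm <= 0 || numerical_aperture <= 0)
    stop("wavelength_nm and numerical_aperture must be positive")
  1.22 * (wavelength_nm / 1000) / numerical_aperture
}

#' Axial resolution (FWHM of the axial PSF) of a confocal system
#'
#' Combines, in quadrature, a diffraction term
#' `0.88 * lambda / (n - sqrt(n^2 - NA^2))` and a pinhole term
#' `sqrt(2) * n * PH / NA`, where `PH` is the backprojected pinhole
#' diameter (`pinhole_au` Airy units). This is the standard confocal
#' optical-slice thickness formula; the diffraction-only limit (closed
#' pinhole) is available with `diffraction_only = TRUE`.
#'
#' @param config An [optical_config()].
#' @param diffraction_only If `TRUE`, return the pinhole-free diffraction
#'   term alone.
#' @return Axial FWHM in micrometres.
#' @examples
#' axial_fwhm(optical_config(561, 0.75, 1.0, 1.2))
#' @export
axial_fwhm <- function(config, diffraction_only = FALSE) {
  stopifnot(inherits(config, "optical_config"))
  lam <- config$wavelength_nm / 1000
  na <- config$numerical_aperture
  n <- config$immersion_ri
  diffr <- 0.88 * lam / (n - sqrt(n^2 - na^2))
  if (diffraction_only) return(diffr)
  ph <- config$pinhole_au * airy_unit_diameter(config$wavelength_nm, na)
  pin <- sqrt(2) * n * ph / na
  sqrt(diffr^2 + pin^2)
}

#' Fresnel reflectance of an interface at normal incidence
#'
#' `((n1 - n2) / (n1 + n2))^2`: the fraction of incident intensity
#' reflected by a refractive-index step. This is the physical origin of
#' the bright background at a glass--medium interface in reflection
#' confocal imaging, and of its suppression when the interface is
#' index-matched.
#'
#' @param interface An [ri_interface()].
#' @return Reflectance fraction in `[0, 1)`.
#' @examples
#' fresnel_reflectance(ri_interface(1.5255, 1.333))
#' @export
fresnel_reflectance <- function(interface) {
  stopifnot(inherits(interface, "ri_interface"))
  n1 <- interface$ri_incident
  n2 <- interface$ri_transmitted
  ((n1 - n2) / (n1 + n2))^2
}

#' Effective numerical aperture through an index-matching layer
#'
#' Rays more oblique than the layer's critical angle are totally
#' internally reflected at the immersion/layer boundary, so a layer of
#' refractive index below the objective NA clips the aperture:
#' `min(NA, n_layer)` whenever the layer has nonzero thickness.
#'
#' @param numerical_aperture Objective NA (> 0).
#' @param layer An [imm_layer()].
#' @return The effective NA (dimensionless).
#' @examples
#' effective_na(1.4, imm_layer(1.33, 20))   # 1.33
#' @export
effective_na <- function(numerical_aperture, layer) {
  if (numerical_aperture <= 0) stop("numerical_aperture must be positive")
  stopifnot(inherits(layer, "imm_layer"))
  if (layer$thickness_um > 0) min(numerical_aperture, layer$refractive_index)
  else numerical_aperture
}

#' Minimum IMM layer thickness for reflection-free optical slices
#'
#' An optical slice centred at the IMM--liquid interface must not overlap
#' the glass--IMM interface, so the layer must be at least one axial FWHM
#' thick.
#'
#' @param axial_fwhm_um Axial FWHM (z-resolution) in micrometres (> 0).
#' @return Minimum thickness in micrometres (equal to the input).
#' @export
min_imm_thickness <- function(axial_fwhm_um) {
  if (!is.numeric(axial_fwhm_um) || axial_fwhm_um <= 0)
    stop("axial_fwhm_um must be positive")
  axial_fwhm_um
}

#' Summarize the optics of a confocal/IMM configuration
#'
#' Convenience wrapper returning all closed-form optics quantities for
#' one configuration as a named list (the payload of the `optics` CLI
#' subcommand).
#'
#' @param config An [optical_config()].
#' @param layer An [imm_layer()], or `NULL` for no layer.
#' @param glass_ri Refractive index of the substrate glass.
#' @param medium_ri Refractive index of the liquid medium.
#' @return Named list with `airy_unit_um`, `axial_fwhm_um`,
#'   `effective_na`, `min_imm_thickness_um` and `fresnel_reflectance`
#'   (of the glass--medium interface, i.e. the uncoated background).
#' @export
optics_summary <- function(config, layer = NULL, glass_ri = 1.5255,
                           medium_ri = 1.333) {
  stopifnot(inherits(config, "optical_config"))
  fw <- axial_fwhm(config)
  ena <- if (is.null(layer)) config$numerical_aperture
         else effective_na(config$numerical_aperture, layer)
  list(
    airy_unit_um = airy_unit_diameter(config$wavelength_nm,
                                      config$numerical_aperture),
    axial_fwhm_um = fw,
    effective_na = ena,
    min_imm_thickness_um = min_imm_thickness(fw),
    fresnel_reflectance = fresnel_reflectance(ri_interface(glass_ri, medium_ri))
  )
}
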