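---
title: "Quantifying biofilm architecture from reflection confocal z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm architecture from reflection confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmbiofilm)
```

## The measurement problem

Confocal reflection microscopy (CRM) images microbial cells by the light
they backscatter, with no fluorescent tag. This matters most where tags
fail: bacteria growing anaerobically (for instance *Pseudomonas
aeruginosa* respiring nitrate) cannot mature the common fluorescent
proteins, so tag-free imaging is the only practical window on their
biofilm architecture. The catch is the substrate: the refractive-index
(RI) step between coverslip glass (n ≈ 1.53) and the aqueous medium
(n ≈ 1.333) reflects a fraction

$$R = \left(\frac{n_1 - n_2}{n_1 + n_2}\right)^2$$

of the incident light straight back into the detector — about
4.5 × 10⁻³ for glass/water, enough to saturate the detector at the
interface and drown the much weaker cell reflections. Coating the glass
with a thin index-matching material (IMM, n ≈ 1.33, e.g. a fluorinated
acrylic polymer or a hydrogel) suppresses that reflection by three to
four orders of magnitude, and cells sitting directly on the surface
become visible.

This package implements the full quantitative pipeline downstream of such
imaging — interface localization, background quantification, 3D
single-cell segmentation, per-cell orientation morphometrics and local
cell-density profiling — together with the closed-form optics of the
confocal/IMM configuration, and a synthetic-scene simulator that renders
CRM-like z-stacks from known ground truth so every estimator can be
validated by parameter recovery.

## Optics of the confocal/IMM configuration

`optical_config()` holds wavelength, objective NA, immersion RI and
pinhole size (in Airy units, AU = 1.22 λ/NA, `airy_unit_diameter()`).
Three design rules matter for an IMM experiment:

* **Axial resolution.** `axial_fwhm()` uses the standard confocal
  quadrature form: a diffraction term
  $0.88\,\lambda / (n - \sqrt{n^2 - \mathrm{NA}^2})$
  combined with a pinhole term $\sqrt{2}\, n\, \mathrm{PH} / \mathrm{NA}$
  (PH = backprojected pinhole diameter). The literature contains several
  competing closed forms that differ by tens of percent at high NA; the
  quadrature form is therefore exposed as the documented default with a
  `diffraction_only` variant, rather than hidden as a constant.
* **Minimum layer thickness.** An optical slice centred on the IMM–liquid
  interface must not overlap the glass–IMM interface, so the layer must
  be at least one axial FWHM thick (`min_imm_thickness()`).
* **Effective NA.** Rays steeper than the IMM's critical angle are
  totally internally reflected before reaching the sample, so a layer of
  RI below the objective NA clips the aperture:
  `effective_na()` returns min(NA, n_layer) for any layer of nonzero
  thickness. An NA 1.4 oil objective behind a 20 µm n = 1.33 layer acts
  as an NA 1.33 objective:

```{r}
effective_na(1.4, imm_layer(1.33, 20))
optics_summary(optical_config(561, 1.4, 1.515, 1.2), imm_layer(1.33, 20))
```

## What the simulator emulates — and what it does not

`scene_spec()` + `sample_scene()` + `rasterize_cells()` +
`render_stack()` generate a ground-truthed stand-in for raw CRM data.
The model, chosen term by term to mirror the physics that the analysis
must cope with:

* **Cells are spherocylinders** (capsules), the simplest convex body with
  a well-defined long axis, with tip-to-tip length uniform on 3–10 µm
  (the filamentous-cell range under denitrifying growth) and diameter
  0.8 µm (a typical *P. aeruginosa* width; a package default, not a
  measured value).
* **Two orientation models.** `"layered"` draws the pitching angle — the
  angle between the cell's long axis and the horizontal plane — from a
  half-normal distribution with scale `pitch_sigma_deg` and quantizes
  centroid z to layers (`layer_spacing_um` = 1 µm by default, one cell
  diameter plus clearance), emulating laminated quasi-horizontal sheets
  ("2D mesh"). `"isotropic"` draws axes uniformly on the upper
  hemisphere, so P(pitch < θ) = sin θ — the randomly oriented "3D mesh"
  null against which layering is detected. The half-normal has mean
  σ√(2/π): σ = 16.8° gives a population mean of 13.4°, and σ = 19.8°
  puts 87 % of the mass below 30°, the two reference operating points used in the recovery tests.
* **Placement.** Axis and length are drawn once per cell and never
  resampled during placement retries, so overlap rejection cannot bias
  the orientation distribution. `overlap_policy = "reject"` enforces
  non-intersection (optionally with `min_gap_um` clearance);
  `"allow"` permits interpenetration for dense-mesh scenes.
* **Image formation.** intensity = baseline + cell term + interface term,
  blurred by a separable anisotropic Gaussian PSF, then Poisson shot
  noise, Gaussian read noise, and clipping to the saturation level. The
  interface term is an x,y-uniform axial Gaussian at z = 0 with amplitude
  proportional to the Fresnel reflectance — a documented approximation of
  the true axial PSF shape. Defaults put the simulator at a plausible
  12-bit operating point: baseline ≈ 86 a.u., cell interiors ≈ 1370 a.u.
  (cell-to-background ≈ 16 over an index-matched surface), and a
  glass–water interface that saturates.

Not emulated: coherent speckle, multiple scattering, spherical
aberration, depth-dependent attenuation, cell growth between timepoints
(time series are independent scenes). Passing recovery tests therefore
demonstrates that the estimators are unbiased under this forward model,
not that segmentation would be artifact-free on heavily aberrated real
data.

## Segmentation

`segment_cells()` is deliberately minimal and fully deterministic:
global Otsu threshold → binary opening (radius 1) → 3D connected
components (26-connectivity) → minimum-volume filter (0.5 µm³) →
deterministic relabeling by first voxel. Three guards matter:

* Slices below `exclude_slices_below_um` are excluded from threshold
  statistics *and* forced to background, so a saturated glass plane
  cannot absorb every surface cell into one component. The default is
  1 µm, the convention of analysing from +1 µm when the interface
  saturates; for index-matched stacks, where the interface is dark, use
  0.
* An Otsu split whose foreground does not exceed the background by at
  least 3 background standard deviations is treated as "no foreground":
  on a baseline+noise-only stack Otsu would otherwise bisect the noise
  distribution and label half the volume.
* Touching cells merge; the pipeline reports merges rather than
  inventing a splitting criterion (no watershed). Recovery experiments
  that need every cell resolved individually generate scenes with
  `min_gap_um` of about one cell diameter.

`locate_interface()` finds the interface as the z-slice of maximal mean
intensity (inside a reflective mark region if one is given), taking the
centre of the plateau when saturation flattens the peak, and falls back
to the declared z-origin with a `no_peak` flag when no peak rises to
twice the median slice mean — the signature of an index-matched stack.

## Morphometrics

`measure_cells()` computes, per component, the eigen-decomposition of
the covariance of physical voxel coordinates. The principal axis is the
leading eigenvector; the pitching angle is arcsin(|axis_z|) ∈ [0°, 90°],
invariant to the physically meaningless axis sign. Elongation is
√(λ₁/λ₂); components below 1.2 are flagged isotropic and excluded from
angle statistics (pitch is only meaningful for elongated cells; 1.2 is the
package's explicit cutoff), as are degenerate components (< 4 voxels or coplanar).
On 0.1 µm isotropic grids, single-spherocylinder pitch recovery is
accurate to well under 2° across 0–90°.

Local cell density is the area occupation rate: labeled-voxel fraction
per z-slice inside a region of interest (`occupancy_profile()`), with
`density_heatmap()` tiling the field into 2.4 µm squares (edge tiles
normalized by their own area, so the tile-weighted mean equals the field
occupancy exactly). The microcolony ROI default — bounding rectangle of
the labeled projection dilated by one cell diameter — is a reproducible
stand-in for a manually outlined microcolony region; "bottom",
"mid-height" and "top" of a colony are operationalized as the 10th, 50th
and 90th percentile occupied slices. `signal_background_ratio()` samples
20 three-by-three-voxel patches per class (seeded, without replacement)
on the slice +1 µm above the interface.

## A complete worked run

```{r}
spec <- scene_spec(extent_um = c(25, 25, 8), cell_count = 25,
                   orientation_model = "layered", pitch_sigma_deg = 16.8,
                   min_gap_um = 0.8, max_placement_attempts = 1000,
                   seed = 42)
sim <- simulate_stack(spec, imaging_spec(poisson_gain = 10,
                                         read_noise_sd = 1, seed = 42))
labels <- segment_cells(sim$stack,
                        segmentation_params(exclude_slices_below_um = 0))
cells <- measure_cells(labels)
angle_summary(cells$pitch_deg, c(30, 45))
occ <- occupancy_profile(labels, colony_roi(sim$truth$labels))
head(occ[occ$occupancy > 0, ])
```

The same pipeline runs from a YAML experiment file via
`run_experiment()` (or the `inst/cli/crm.R` command-line wrapper), which
writes the rendered stack, ground truth, measurement tables, a summary
JSON, figures and a run manifest recording the derived random streams.

## Numerical and design choices

* One integer seed per run fans out to independent scene / noise /
  SBR-sampling streams, so re-noising a fixed geometry is possible and
  reproducibility is end-to-end (noise-free runs are byte-identical).
* Volumes are `(y, x, z)` arrays; x/y voxel centres sit at
  (i − ½)·pitch and z-slice centres at (k − z_origin)·dz, so one slice
  lies exactly on the interface plane (no argmax ties at a symmetric
  peak).
* Stacks are stored as 16-bit multi-page TIFF with a JSON sidecar for
  voxel size and z-origin; 16-bit quantization is ≤ 1 a.u.
* The PSF blur uses truncated (4σ) kernels renormalized at the borders,
  so constant fields — notably the detector baseline — are preserved
  exactly.
* Recovery experiments in the tests and the acceptance script use scenes
  of 300–500 cells in 60–70 µm fields at 0.15 × 0.15 × 0.2 µm voxels,
  chosen so Monte-Carlo standard errors sit well inside the recovery
  tolerances while a full run stays in the tens of seconds.
* Occupancy operating points are set by a calibration loop
  (`calibrate_scene_occupancy()`) that adds cells until the ground-truth
  rasterization reaches the target mid- or top-slice occupancy — the
  oracle is the rasterizer itself, so the target is exact by
  construction.

## Known limitations

* No splitting of touching filaments; in dense meshes the per-cell
  statistics apply only to resolvable components (merges bias pitch
  slightly toward the horizontal).
* The axial-resolution formula is one of several published variants;
  z-resolutions quoted for specific instruments may differ from it by
  tens of percent, which is why such values are treated as documentation
  cross-checks rather than assertions.
* The simulator's intensity scale is uncalibrated (arbitrary units);
  absolute intensities are meaningful only as ratios, and the
  defaults are plausible operating points rather than calibrated values.
* Steep cells in the layered model are clamped into the domain after
  layer snapping, which can break layer quantization for the rare cell
  with pitch near 90°.
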