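# crmbiofilm

Quantitative analysis of biofilm microcolony structure from **confocal
reflection microscopy (CRM)** z-stacks — the tag-free imaging mode that
works where fluorescent proteins cannot (e.g. *Pseudomonas aeruginosa*
biofilms grown anaerobically under denitrifying conditions).

CRM detects backscattered incident light. On plain glass the
refractive-index step to the medium reflects
`R = ((n1 - n2) / (n1 + n2))^2` of the beam (≈ 4.5 × 10⁻³ for
glass/water), saturating the detector at the interface; a thin
**index-matching material (IMM)** layer (n ≈ 1.33) suppresses this
background so cells on the surface become measurable. This package
provides everything downstream of such imaging:

* **Optics** — Airy unit, axial FWHM (quadrature of the diffraction term
  `0.88 λ / (n − √(n² − NA²))` and the pinhole term `√2 · n · PH / NA`),
  Fresnel reflectance, effective NA through an IMM
  (`min(NA, n_layer)` by total internal reflection) and the minimum
  layer thickness rule.
* **Segmentation** — interface localization, background estimation,
  Otsu threshold with a noise guard, 3D connected components,
  volume filtering; all deterministic.
* **Morphometrics** — per-cell principal axis from second moments of
  voxel coordinates, **pitching angle** `arcsin(|axis_z|)` ∈ [0°, 90°]
  (angle between the cell's long axis and the interface plane),
  elongation, area occupation rate per z-slice, 2.4 µm density
  heatmaps, axial intensity profiles and signal-to-background ratios.
* **Simulator** — spherocylinder cell scenes under a *layered*
  (half-normal pitch, laminated "2D-mesh") or *isotropic* (hemisphere
  uniform, "3D-mesh", P(pitch < θ) = sin θ) orientation model, rendered
  into CRM-like stacks with interface reflection, anisotropic Gaussian
  PSF, shot/read noise and saturation — the ground truth against which
  every estimator is recovery-tested.
* **Pipeline** — YAML-configured simulate → analyze → report runs with
  manifests and seeded substreams (`run_experiment()`), plus a thin CLI
  (`inst/cli/crm.R`).

## Worked example

Simulate a small layered microcolony, segment it, and measure cell
orientations and density:

```r
library(crmbiofilm)

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
#> $n
#> [1] 25
#> $mean_deg
#> [1] 16.76749
#> $fraction_below
#> lt_30 lt_45
#>  0.80  0.96
```

All 25 cells are recovered as single components; the estimated mean
pitch (16.77°) matches the scene's true mean (16.75°), and 80 % of the
cells lie below 30° — the quasi-horizontal signature of a laminated
mesh (an isotropic colony would put only 50 % below 30°). The optics of
the acquisition are summarized in closed form:

```r
optics_summary(optical_config(561, 1.4, 1.515, 1.2), imm_layer(1.33, 20))
#> $airy_unit_um          0.4888714
#> $axial_fwhm_um         1.041254
#> $effective_na          1.33
#> $min_imm_thickness_um  1.041254
#> $fresnel_reflectance   0.004535081
```

i.e. a 561 nm, NA 1.4 oil objective behind a 20 µm n = 1.33 layer acts
as an NA 1.33 objective, and the layer must be at least one axial FWHM
thick to keep the glass reflection out of the optical slice.

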