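# poremorph

Porosity morphometry of porous membranes from single SEM cross-section images.

## The problem

Artificial porous membranes — scaffolds for tissue cultivation, filtration
membranes, encapsulation barriers — owe much of their biomedical utility to
their 3D pore structure: the size, shape, density and spatial distribution of
the cavities and channels penetrating the material. Porosity is a 3D property,
but in practice (fragile specimens, no access to serial sections) the evidence
is often a *single* 2D scanning electron microscope image of a cross-section,
in which pores appear as dark, irregularly shaped regions over a bright
background. `poremorph` implements a combined morphological–statistical
pipeline that extracts the missing third dimension from exactly this kind of
image, for image analysts and membrane scientists who cannot use stack-based
methods (FIB, serial block face).

## The method

Working in discrete 2D/3D space with an explicit connectivity convention
(4/8 in 2D, 6/26 in 3D), the package measures each pore section's contour
length *L* (pix), area *S* (pix²) and **regularity coefficient**

> η = 4π·S / L²,

equal to 1 for a Euclidean circle and decreasing toward 0 with increasing
irregularity (a 3D analogue γ = κ·V/√S³ is provided for volumes). The third
dimension is then estimated by two independent routes:

1. **Statistical chord extension.** Each pore section is cut into horizontal
   strips of breadth δ; each strip is modeled as a flat elliptic cylinder with
   in-plane axis the strip chord *lᵢ* and out-of-plane axis *gᵢ* inferred —
   under the assumption of 3D morphological isotropy — from the lengths of
   vertical chords crossing the strip (mean, or modal value via adaptive
   sub-interval binning). Strip volumes vᵢ = (π/4)·δ·lᵢ·gᵢ accumulate into
   per-pore volumes, the specimen total V_Σ, the density ρ = V_Σ/V, and the
   mean/spread of pore volume (m_V, Δ_V).
2. **Brightness profiles.** Assuming brightness decreases linearly with pore
   depth, the depth of each pixel is ζ(β) = D_max·(1 − β/(255−ε)), where ε is
   the brightness margin separating pores from background (estimated from the
   coarse brightness histogram) and D_max the maximal expected depth
   (estimated as the longest dark run along line profiles). Then
   V_Σ = Σζ and ρ = V_Σ/V.

A seeded synthetic-scene generator (ellipsoidal pores in a slab, rendered as
cross-sections or depth-shaded images with exact ground truth) makes every
stage testable end to end.

## Worked example

```r
library(poremorph)

scene <- generate_scene(n_pores = 6, dims = c(160, 160, 40),
                        axis_meanlog = log(13), axis_sdlog = 0.15, seed = 42)
sect <- render_scene(scene, "cross-section")
seg  <- segment_pores(sect$image, epsilon = 10)
est  <- estimate_volumes(seg, delta = 1, method = "mean")
print(est)
#> volume_estimate (mean method): 5 pore(s)
#>   V_sigma = 6.87e+04 pix^3, V_ref = 8.704e+05 pix^3, rho = 0.07893
#>   m_V = 1.374e+04 pix^3, Delta_V = 4440 pix^3

rd <- render_scene(scene, "depth-render")
dm <- depth_map(rd$image, depth_model(epsilon = 10, d_max = 40))
print(dm)
#> depth_map: V_sigma = 6.912e+04 pix^3, V_ref = 1.024e+06, rho = 0.0675 (consistent mode)
scene$true_density
#> [1] 0.06753417
```

The chord route reports per-pore volumes, their mean `m_V` and spread
`Delta_V`, and a density `rho` relative to a stated reference volume (frame
area × reference depth); the depth route integrates the brightness-decoded
depth field — here recovering the generator's true density 0.0675 almost
exactly. The two densities use different reference-volume conventions and are
comparable across specimens only at equal settings ([`compare_reports()`]
enforces this).

A thin command-line wrapper is installed at `inst/cli/poremorph.R`:

```sh
Rscript inst/cli/poremorph.R synth   --outdir demo --seed 7
Rscript inst/cli/poremorph.R analyze --input demo/section.png --outdir demo-out
Rscript inst/cli/poremorph.R table1     # digitized-circle regularity self-check
```

## Not in scope

SEM acquisition and specimen preparation, stack-based 3D methods (FIB/SBF),
fractal shape description, watershed splitting of merged pores, and any
biological interpretation of membrane quality.
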