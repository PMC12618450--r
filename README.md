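# hygrobone

Swelling co-polymeric bone anchors fix themselves in trabecular bone by an
expansion-fit mechanism: the hydrophilic polymer absorbs interstitial
fluid, swells inside its press-fit drill hole, and generates compressive
radial pressure at the bone–implant interface.  That pressure is both the
source of Coulomb frictional fixation and a mechanical stimulus that can
drive bone remodeling — densification when the stimulus is moderate,
overload resorption when the swelling is excessive.

`hygrobone` is a desk-scale R implementation of that coupled problem, for
biomechanics researchers who want to study composition choices (MMA/AA
ratios 80/20, 85/15, 90/10) without commercial FE software or micro-CT
data.  It provides:

* a **synthetic trabecular micro-CT generator** (Gaussian random field,
  thresholded at the quantile matching a target bone volume ratio) with
  drill-defect and anchor insertion, so every stage is testable without
  scan data;
* **HU-based material calibration**: apparent density
  `rho = (1041395 + 1017·HU)·1e-6 g/cm³` and elastic modulus
  `E = (-388.8 + 5925·rho[g/m³])·1e-6 MPa`, with optional 10-type binning;
* a **voxel-mesh linear-elastic FE solver** (bilinear quads / trilinear
  hexahedra, sparse Cholesky) with isotropic hygroscopic eigenstrain
  loading `eps_hs = beta_h · (alpha_m − alpha_m,ref)`;
* the **strain-energy-density remodeling law** with lazy zone and
  quadratic overload resorption,

  ```
  drho/dt = B(S − (1+δ)k) − D(S − (1+δ)k)²   if S > (1+δ)k
          = 0                                 inside the lazy zone
          = B(S − (1−δ)k)                     if S < (1−δ)k
  ```

  with stimulus `S = U/rho` (J/g), integrated by forward Euler with
  clamping to `[0.01, 2] g/cm³` (defaults `B = 1`, `D = 60`,
  `k = 0.004 J/g`, `δ = 0.1`, `Δt = 0.01`);
* **bone-volume-ratio morphometry** (hollow-cylinder interface ROI vs
  equal-volume far-field spheres, paired t-test) applied to HU projections
  of the remodeled fields;
* a **Coulomb push-out estimate** `F = μ Σ max(p_i, 0) A_i` (μ = 0.4)
  comparing pre- and post-remodeling fixation.

## Worked example

Free swelling of an 8 mm anchor must match the closed form
`Δd = d₀·β·Δα` to machine precision (an FE patch test):

```r
library(hygrobone)
run_free_swelling()
#>   composition fe_d_diameter closed_d_diameter rel_err_diameter
#> 1       80/20      1.848948          1.848948      6.00462e-16
#> 2       85/15      0.688210          0.688210      3.22641e-16
#> 3       90/10      0.351887          0.351887      3.15506e-16
```

So a fully swollen 80/20 anchor grows 1.85 mm in diameter, 85/15 grows
0.69 mm, 90/10 grows 0.35 mm — the composition controls the swelling dose.

A single bone element whose strain energy is frozen at `U = 0.008 J/cm³`
remodels until its stimulus falls to the upper lazy-zone edge
`(1+δ)k = 0.0044 J/g`, i.e. to `rho = U/0.0044`:

```r
remodel_fixed_energy(1.0, 0.008)[c("rho", "S", "steps")]
#> $rho 1.818182   $S 0.0044   $steps 1052539
```

The packaged 2D demo (synthetic trabecular disc, Ø20 mm, ~5000 elements,
press-fit 8 mm anchor) runs the full pipeline:

```r
res <- run_pipeline(default_pipeline_config("85/15"), out_dir = "run")
#> interface density: 1.210 -> 1.588 g/cm3   (converged, 192 checkpoints)
#> BVR interface 1.000 vs far 0.284
#> push-out 114.26 -> 114.31 N/mm (+0.05%)
```

The moderate 85/15 swelling densifies the 2-mm interface shell from 1.21
to 1.59 g/cm³ (46 elements reach the density cap), the interface bone
volume ratio ends far above the far field, and the post-remodeling
push-out force exceeds the pre-remodeling one.  Running the same demo
with `"80/20"` instead floors hundreds of interface elements (overload
resorption) and degrades fixation; `"90/10"` changes the interface only
marginally.  `out_dir` receives VTK fields, CSV tables, a text report and
a JSON parameter echo.

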