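# atflap

Preoperative evaluation of **A-T (O-T) advancement flaps**: a closed-form
geometric design model plus a 2-D nonlinear finite-element simulation of the
closure, in pure R.

The A-T flap closes a roughly circular skin defect by excising it as a
triangle, extending the incision along the triangle base, and advancing the
two lateral skin sheets until the triangle waists meet on the midline (the
scar is T-shaped). Flap design is traditionally experience-driven; `atflap`
is aimed at surgeons and biomechanics researchers who want the design
quantified before the first cut.

Two layers:

1. **Geometric design model.** With defect radius `r` and half-apex angle
   `θ` (apex angle `2θ`):

   - length–width ratio `h/d = 1/(2 tan θ)`
   - maximum suture distance `d = 2r(1 + sin θ)/cos θ`
   - suture area `S = r²(1 + sin θ)²/(sin θ cos θ)`

   `S` has a closed-form minimum at `sin θ = 1/2`: the optimal apex angle is
   exactly **60°**, where the excision triangle is equilateral.

2. **Finite-element simulation.** A total-Lagrangian plane-stress solver for
   incompressible Ogden hyperelasticity (thickness stretch `λ₃ = 1/det F`,
   pressure eliminated via `σ₃₃ = 0`) on a block-structured quadrilateral
   mesh of the 90 × 100 mm operative region, with duplicated nodes along the
   incision cuts. Two analysis stages: *suture* (prescribed displacements
   close the wound onto the T midline) and *release* (prescribed
   displacements swapped for tie constraints, reaction forces ramped to
   zero), reporting von Mises stress and displacement fields.

## Worked example

```r
library(atflap)

flap_sweep(10, c(40, 50, 60, 70, 80))
#>   apex_deg ratio  d_mm  S_mm2 S_norm  h_mm
#> 1       40  1.37 28.56 560.38   5.60 39.24
#> 2       50  1.07 31.39 528.39   5.28 33.66
#> 3       60  0.87 34.64 519.62   5.20 30.00
#> 4       70  0.71 38.42 527.01   5.27 27.43
#> 5       80  0.60 42.89 548.08   5.48 25.56

optimal_apex()   # apex angle minimizing suture area s.t. h/d <= 3
#> [1] 60
```

A 10 mm defect at the optimal 60° apex needs a flap of width
`d = 34.64 mm` and length `h = 30 mm`; the 60° row has the smallest suture
area. (`S_norm` is `S/r²` — the scale on which design tables are usually
printed.)

The full simulation:

```r
rep <- run_pipeline(simulation_config())   # r = 10 mm, apex 60°, 3 mm mesh
rep
#> A-T flap simulation report
#>   design : r = 10 mm, apex = 60 deg, h = 30.00 mm, d = 34.64 mm, S = 519.6 mm^2
#>   mesh   : 1254 elements, 1356 nodes (0 inverted, 0 distorted, 548 bad aspect)
#>   suture : max vM 55.464 MPa at (17.3, 0.0), max |u| 17.932 mm at (-17.3, 0.0)
#>   release: max vM 26.761 MPa at (17.3, 0.0), max |u| 18.175 mm at (17.3, 0.0)
```

Reading the report: the peak stress sits at a base-corner/T-joint node —
one of the clinically expected concentration sites (defect apex, central
suture joint, lateral "cat-ear" ends) — and releasing the external load
roughly halves it, while the sutured seam stays closed. The peak
displacement is set by the closure geometry itself: the base corners must
travel `d/2 = 17.3 mm` to meet at the midline. Mesh-sensitivity runs at
{4, 3, 2, 1} mm (`mesh_sensitivity_study()`) all mesh with zero inverted
elements; the release-stage peak displacement changes by 0.2 % between the
two finest meshes, while the peak stress is corner-singular and is not
expected to converge.

A command-line wrapper ships in `inst/cli/`:

```sh
atflap design --radius 10 --apex 60
atflap sweep  --radius 10 --apex-list 40,50,60,70,80 --out table.csv
atflap simulate --out results/       # writes VTK fields, CSV, JSON report
```

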