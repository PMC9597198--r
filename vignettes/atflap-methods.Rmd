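---
title: "Geometric design and finite-element evaluation of A-T advancement flaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric design and finite-element evaluation of A-T advancement flaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atflap)
```

## The clinical problem

The A-T (O-T) flap is a local advancement flap used to close roughly
circular skin defects, particularly on the face. The lesion is excised as a
triangle ("A"), the incision is extended laterally along the triangle base,
and the two lateral skin sheets are advanced medially until the triangle
waists meet on the midline; the scar is T-shaped. The design is governed by
one free parameter — the apex angle `2θ` of the excision triangle — and
`atflap` provides both the closed-form geometric design model that selects
it and a nonlinear plane-stress finite-element model of the suture and
release stages of the closure.

## Geometric design model

The defect is idealized as a circle of radius `r` inscribed in the excision
triangle (tangent to the base and to both waists).  Elementary geometry
gives the three design quantities as functions of the half-apex angle `θ`:

- length–width ratio `h/d = 1/(2 tan θ)`, strictly decreasing in `θ`;
- maximum suture distance (base width) `d = 2r(1 + sin θ)/cos θ`,
  strictly increasing;
- suture (excision) area `S = r²(1 + sin θ)²/(sin θ cos θ)`,
  which equals the triangle identity `d·h/2`.

`S` is unimodal with a closed-form stationary point: the logarithmic
derivative `2cos θ/(1+sin θ) − cot θ + tan θ` vanishes exactly at
`sin θ = 1/2`, so the minimizing apex angle is exactly 60°.  The clinical
bound `h/d ≤ ratio_max` (default 3, protecting flap perfusion) is handled
by unimodality: a binding constraint moves the optimum to the nearest
feasible angle ([optimal_apex()]).

```{r geometry}
flap_sweep(10, c(40, 50, 60, 70, 80))
optimal_apex()
design_flap(10, 60)
```

A note on units: published versions of this design table label the area
column "mm²" but print values around 5.2–5.6, which are the areas
*normalized by `r²`* (equivalently, cm² at `r = 1` cm).  The sweep stores
`S` in true mm² and reports the normalized value as `S_norm`.

The base incision is extended so that its total span is
`base_extension_factor × 2r` (default 3 diameters, the usual clinical rule
of thumb); the small triangular "cat ear" folds at its ends are represented
only as the lateral cuts, not excised.

## Skin material model

Skin is modeled as an isotropic, incompressible hyperelastic solid with an
N-term Ogden strain energy in principal stretches,

`W = Σₙ (μₙ/αₙ)(λ₁^αₙ + λ₂^αₙ + λ₃^αₙ − 3)`, `λ₁λ₂λ₃ = 1`.

The default parameters ([facial_skin_ogden()]) are the two-term facial-skin
set `μ₁ = 7.5809×10⁻⁷ MPa, α₁ = 2.1065, μ₂ = 0.1683 MPa, α₂ = 12.006`
(ground-state shear modulus `G₀ = ½Σμₙαₙ ≈ 1.01 MPa`).  A compressible
variant with a `4.5K(J^{1/3}−1)²` volumetric term is implemented for
completeness, but the solver always uses the incompressible form: no bulk
modulus is needed because plane stress eliminates the pressure analytically
(below).

Closed forms used throughout: uniaxial Cauchy stress
`σ(λ) = Σₙ μₙ(λ^αₙ − λ^{−αₙ/2})` and its nominal counterpart `σ/λ`.  Both
are verified in the test suite against two independent oracles: central
differencing of the one-variable energy, and constrained minimization of
`W` over the lateral stretch ([uniaxial_stress_brute()]), which shares no
code with the closed form.

[fit_ogden()] recovers parameters from a uniaxial stress–stretch curve by
multi-start bounded Levenberg–Marquardt (μ ≥ 0, α ∈ [0.1, 30]; the model is
linear in μ for fixed α, so each start seeds μ by linear least squares).
Because the experimental facial-skin curve behind the default parameters is
not publicly tabulated, fitting is exercised on synthetic curves
([make_stress_stretch_curve()]).  Two-term Ogden models are notoriously
non-identifiable from a single uniaxial arc (note `μ₁ ~ 10⁻⁷`), so fit
quality is judged on the predicted stress curve (RMS residual), never on
parameter recovery; with noise, the residual is bounded by the noise SD.

## Mesh

The operative region is a 90 × 100 mm rectangle (about three flap sizes,
beyond which stresses are negligible), with the origin at the T-junction
and y up.  It is paved block-structured with bilinear quadrilaterals
conforming to the incision: two Coons-patch blocks for the advancing flap
sheets (bounded medially by the waists), a structured strip above the apex
level and one below the base line.  The excised triangle is absent from the
mesh; its waists are the suture margins.  Nodes along the lateral base cuts
are duplicated — one flap-side, one lower-skin-side, coincident in the
reference state — so the flap can slide tangentially over the stationary
lower skin, which is exactly the cat-ear mechanism the lateral incisions
exist for.  No contact is modeled; the cut may slide or open slightly, and
the wound-bed edge of the lower sheet is free.

The default element size is 3 mm, inside the 2–5 mm clinical
suture-bite-stitch interval, giving 1,254 elements / 1,356 nodes.  Meshing
is fully deterministic; quality is reported as the count of inverted
elements (non-positive corner Jacobian — for a bilinear quad the Jacobian
determinant is linear per reference coordinate, so corner values are
extremal), distorted elements (minimum scaled Jacobian, i.e. corner-angle
sine, below 0.5) and bad-aspect elements (edge ratio above 1.5).  All
standard sizes {4, 3, 2, 1} mm mesh with zero inverted elements.

## Suture kinematics

Each left-waist node is paired with its mirror right-waist node; the pair
shares a target on the midline.  The published source of this scenario does
not state its prescribed displacement values, so the mapping is a pluggable
strategy with two options:

- `"isometric"` (default): each waist is rigidly rotated about the apex
  onto the midline.  The seam keeps the waist arc length `L_w` (sutures
  impose no tangential strain on the margins), the apex needs no prescribed
  motion, and the base corners meet at `(0, h − L_w)` — 4.64 mm below the
  base line for the 60° design.
- `"proportional"`: arc-length-proportional mapping onto the apex-to-origin
  segment; the corners meet exactly at the T-junction at the cost of a
  tangential seam compression `h/L_w ≈ 0.87`.

The release equilibrium is identical under both (it is the tied equilibrium
with the external load removed), so the choice affects only the transient
suture state.

## Finite-element solver

A total-Lagrangian displacement formulation on 4-node quadrilaterals with
2×2 Gauss quadrature.  Plane stress with analytic incompressibility: the
thickness stretch is `λ₃ = 1/det F`, and the pressure is eliminated through
`σ₃₃ = 0`, giving principal Cauchy stresses
`σₐ = Σₙ μₙ(λₐ^αₙ − λ₃^αₙ)` reassembled spectrally from `b = FFᵀ`
(eigenvalues clamped at 1e-12 against round-off) and the nominal stress
`P = σF⁻ᵀ` (the full 3-D volume ratio is 1).  This avoids mixed
displacement–pressure elements and any choice of bulk modulus.

The consistent tangent is obtained by central differencing of `P` with
respect to `F` at each quadrature point (`h = 1e-7`): simpler and more
robust than the analytic principal-stretch tangent at coincident stretches,
accurate to ~1e-8, and therefore preserving Newton convergence at the
default residual tolerance (1e-8 relative to each increment's initial
unbalanced force).  Load is ramped over 20 increments with a full Newton
loop per increment, backtracking line search, and step bisection (up to 4)
on divergence or element inversion; element inversion (`det F ≤ 0`) is a
recoverable signal, not a crash.

Two stages model the operation:

1. **Suture**: both dofs of every pair node are prescribed and ramped to
   the pair target; the four domain corner nodes are fixed.  (The model's
   "four corner nodes fixed" is read as the outer skin-rectangle corners,
   leaving the skin margin otherwise free.)
2. **Release**: continued from the converged suture state.  The prescribed
   displacements are replaced by tie constraints — each left node slaved to
   its right partner by exact master–slave condensation (equal displacement
   increments; no penalty parameter) — and the suture-stage reaction forces
   are ramped linearly to zero.  At zero the external load is gone and only
   the sutures (ties) and corner fixings remain.

Stress output: Gauss-point Cauchy stresses are extrapolated bilinearly to
element corners and arithmetically averaged per node; the reported maxima
use the nodal-averaged plane-stress von Mises
`√(σ₁₁² − σ₁₁σ₂₂ + σ₂₂² + 3σ₁₂²)`.  Maxima depend on this recovery choice,
which is why it is fixed and documented.  The solver contains no
randomness; results are bit-reproducible for a fixed configuration.

## What the reference simulation shows — and a known discrepancy

Running the default configuration (`run_pipeline(simulation_config())`,
1,254 elements) yields, on the machine used to develop the package:

- suture: max von Mises 55.5 MPa, max displacement 17.93 mm;
- release: max von Mises 26.8 MPa, max displacement 18.17 mm;
- the peak stress sits at a base-corner/T-joint node, one of the clinically
  expected concentration sites (defect apex, T-joint, cat-ear ends);
- the displacement field is mirror-symmetric, and the tied seam stays
  closed (gap < 1e-6 mm) after release;
- the element-size study at {4, 3, 2, 1} mm meshes cleanly everywhere, and
  the release-stage peak *displacement* changes by only 0.2 % from 2 mm to
  1 mm.  The peak *stress* grows under refinement (22.4 → 52.2 MPa): the
  re-entrant corners make it a singular quantity, so no mesh convergence is
  asserted for it.

The published scenario this reproduces reports far smaller maxima
(suture/release 2.881/1.961 MPa and 7.06/6.297 mm) together with *complete*
defect closure.  These two statements cannot hold simultaneously in any
full-closure kinematics: bringing the base corners of a `d = 34.64` mm
excision to the midline displaces them by at least `d/2 = 17.32` mm,
2.5 times the reported maximum displacement.  Its prescribed displacement
values being unprinted, the published run evidently closed the wound only
partially (with contact machinery bridging the rest).  `atflap` implements
the full closure its own geometric model prescribes and reports the
resulting maxima honestly; the corresponding acceptance comparisons are
expected to disagree with the published numbers, and the package's test
suite documents that disagreement rather than tuning the boundary
conditions toward it.  For the same reason the published
"release displacement < suture displacement" ordering cannot hold here:
tied seam nodes remain on the midline by symmetry (|u| ≥ 17.32 mm at the
corners) while the suture-state maximum is the prescribed 17.93 mm, and the
relaxed T-joint settles ≈ 5.5 mm below the base line.  The *stress*
ordering (release < suture) does hold, at every element size tested.

## Numerical choices and degenerate inputs

- Angles are degrees at every user interface and radians internally; the
  user-facing quantity is the apex angle `2θ`.
- Design-table printing rounds half away from zero to 2 decimals; stored
  values keep full precision.
- `θ` outside `(0°, 90°)`, non-positive `r` or stretches, `det F ≤ 0`,
  infeasible design constraints, meshes whose flap margin is under one
  element size, and tied/prescribed dof collisions all raise immediate,
  specific errors.
- An empty angle list sweeps to an empty table; a zero-stress curve fits to
  a (near-)zero-μ model.

## Scope and limitations

The model is 2-D plane stress on a flat sheet: no skin anisotropy
(Langer lines), no viscoelasticity or creep, no per-patient material
variation, no perforator/blood-supply physiology, no true unilateral
contact or suture-thread mechanics, and no curved-surface (3-D shell)
flaps.  Synthetic stress–stretch curves exercise the fitting machinery but
cannot stand in for experimental inter-subject variability; passing tests
demonstrate internal consistency and faithfulness to the stated model, not
predictive accuracy for an individual patient.
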