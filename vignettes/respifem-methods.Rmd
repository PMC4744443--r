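---
title: "Methods: active muscle continuum mechanics of the breathing thorax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active muscle continuum mechanics of the breathing thorax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respifem)
```

respifem simulates thorax deformation driven by contraction of the
respiratory muscles: the intercostal sheets that rotate the ribs
(bucket-handle and pump-handle motion) and the diaphragm dome whose descent
draws air into the lungs. This vignette records the model, the numerical
method, and the design decisions behind both, so that results produced with
the package can be interpreted — and challenged — precisely.

Throughout, units form a consistent mm–MPa–N system (pressures in MPa;
2 kPa = 2e-3 MPa) and anatomical axes are +x left-lateral, +y ventral,
+z cranial.

## The muscle continuum

Muscle is modelled as an incompressible, transversely isotropic hyperelastic
continuum with an embedded Hill-type fibre. With `C` the right Cauchy–Green
tensor, `J = det F`, and `N` the reference fibre direction, the law depends
on the *reduced* (isochoric) invariants

* `I1bar = J^(-2/3) tr C`, and
* the reduced fibre stretch `lam = sqrt(J^(-2/3) N·CN)`,

so that pure volume change produces no deviatoric response; incompressibility
itself is enforced separately (below). The strain energy is

```
U = c exp(b (I1bar - 3))  +  T0M ∫₁^lam f_PE(s) ds  +  T0M α γ ∫₁^lam f_CE(s) ds
```

* The first term is the isotropic matrix (ground substance);
  `c = 0.009348` MPa and `b = 1.4939` are the respiratory-muscle
  calibration used by default. (A variant of this energy appears in the
  literature with an extra constant factor in the exponent; since an
  additive or multiplicative energy constant is immaterial to stress, the
  package fixes the form above, whose derivative is exactly the matrix
  stress term used in the stress expression.)
* `f_PE(lam) = 2aA(lam-1) exp(a(lam-1)^2)` for `lam > 1`, else 0 — the
  passive parallel element, slack in compression, stiffening in tension.
  The constants `a`, `A` are calibration inputs; the defaults
  (`a = 12.43`, `A = 0.28`) are representative of passive skeletal muscle
  and every shipped verification problem sets them explicitly.
* `f_CE` is the active force–length curve of the contractile element:
  piecewise linear on \[0.6, 1.2), peaking at exactly 1.0 at unit stretch,
  with separate calibrations for the intercostals and the diaphragm
  (`fl_intercostal()`, `fl_diaphragm()`). `T0M = 0.3` MPa is the maximum
  nominal stress; `γ ∈ [0,1]` is the spatial activation level and
  `α(t) ∈ [0,1]` its time course. The active nominal fibre stress is
  `T_CE = T0M f_CE(lam) α γ`, so a fully activated fibre at optimal length
  bears exactly `T0M`.

The second Piola–Kirchhoff stress is the exact gradient of `U` with respect
to the Green–Lagrange strain plus a hydrostatic term `-p C⁻¹`. "Exact"
matters: the derivatives of the reduced invariants carry `J^(-2/3)` factors
that only disappear under exact incompressibility, and the package keeps
them so that stress and energy are consistent to machine precision at *any*
admissible state — this is enforced by a finite-difference oracle in the
test suite (50 random states, relative error < 1e-6). Two properties worth
knowing:

* At the reference configuration a passive muscle is exactly stress-free.
* An *activated* muscle at unit stretch is not: it carries the deviatoric
  fibre stress `T0M (N⊗N − I/3)`. That is the model's representation of
  active tension, not an artefact.

The force–length curves are retained exactly as calibrated, including their
kinks and the discontinuous drop to zero at the upper end of the support.
An optional, explicitly logged taper (`fl_taper()`, `fl_smooth` in
`muscle_params()`) is available for solver robustness but is never applied
by default.

Passive tissues (bone, cartilage, tendon, central tendon) use a Saint
Venant–Kirchhoff law, `S = λ tr(E) I + 2μ E`: linear in the Green–Lagrange
strain, hence a faithful finite-strain extension of the linear elasticity
these tissues are usually assigned (bone μ = 569.23, λ = 853.85 MPa;
cartilage 65.38, 98.08; tendon 5.18, 10.05). At the small strains these
stiff regions experience the choice of finite-strain extension is
immaterial.

## Mixed displacement–pressure elements

Meshes are 4-node tetrahedra with constant strain and single-point
quadrature. Each node carries three displacement DOFs; each muscle element
carries one incompressibility multiplier `ξ` enforcing `det C = 1` in the
weak sense (a P1–P0 mixed pair). The multiplier is the hydrostatic pressure
up to a factor: `p = -2ξ`, an identity the solution history exposes
directly. Passive regions are treated as compressible and carry no
multiplier.

P1–P0 is not inf–sup stable, and on the 6-tets-per-hex meshes the
generators produce the per-element constraints outnumber the interior
displacement DOFs, so the saddle-point system is rank-deficient if the
constraints are imposed exactly. The package therefore regularises with a
perturbed Lagrangian: the constraint equation becomes
`det C − 1 = stab · ξ`, contributing `-stab·V` to the multiplier diagonal.
`stab` (MPa⁻¹; `options$stab` of `fe_model()`) trades volume error for
locking: the converged per-element volume error is about `stab · |ξ|`.
The default `stab = 1e-3` keeps volume errors near 1e-5 for the
verification problems; the thin-sheet demonstration scenarios raise it
(0.01–0.1, stated per scenario) because one-element-thick muscle sheets
lock severely otherwise, and a relative volume error of a few percent is a
better-balanced discretisation error there than an artificially rigid
sheet.

Pressure loads are follower loads: the consistent nodal forces of a uniform
pressure on the *deformed* surface, with the corresponding (unsymmetric)
load tangent. Physiological pressures act normal to the moving wall, which
is what this models; a dead-load mode (`follower = FALSE`) exists for
verification. Sign convention: positive magnitude pushes against the
outward normal (into the solid), so abdominal pressure below the diaphragm
is positive and the sub-atmospheric pleural pressure is negative (suction).

## Solution procedure

Loading is incremental-static (inertia omitted): the schedule span is
divided into `n_increments`, pressures ramp linearly across it, and the
activation waveform `α(t)` is evaluated at each increment. Each increment
is solved by Newton iteration with the consistent analytic tangent
(including the follower-load and contact blocks), a backtracking line
search on the residual norm, and rejection of steps that invert an element.
Convergence demands a reduced residual below
`max(newton_abs_tol, newton_tol · r₀)` with `r₀` the increment's first
residual (defaults 1e-10 N and 1e-8).

The piecewise-linear force–length curves make the equations non-smooth:
when many fibre stretches sit exactly on curve breakpoints, the line search
can stall at a small, irreducible residual. `stall_tol` (off by default)
accepts such iterates when the absolute force residual is below the given
threshold; the scenarios use 1e-3 N against load scales of tens of N and
mark the affected increments (`stalled`) in the history. On smooth
configurations the solver exhibits the expected quadratic convergence, and
the test suite checks the rate.

Contact with the chest wall is frictionless node-to-surface against a rigid
triangulated master, enforced with Lagrange multipliers under the
Karush–Kuhn–Tucker conditions `g ≥ 0`, `η ≤ 0`, `g·η = 0` (gap,
compressive force, complementarity). An active-set strategy is used: after
each converged Newton solve, penetrating nodes (`g < -gap_tol`) enter the
active set and nodes with tensile multipliers leave it, and the increment
is re-solved until the set is stable. Active multipliers are solved
monolithically with displacements and `ξ`. The master is rigid by design:
at toy scale the chest wall target is fixed, and a deformable master is out
of scope.

## Synthetic geometries: what they emulate, and what they do not

No patient anatomy ships with the package; all inputs are generated.

**Strip** (`make_strip()`): a fibre-aligned box, the fixture for material
point, patch-test, and uniaxial verification. The closed-form incompressible
uniaxial solution (pressure eliminated from the lateral zero-stress
condition) is the oracle for both the passive stretch response and the
active clamped reaction `T0M · f_CE(1) · A`.

**Rib cage toy** (`make_two_rib_toy()`): curved rib beams (bone) joined by
oblique-fibre muscle sheets, symmetric about the ventral midline, dorsal
ends at the vertebrae. Key anatomical features retained, each of which
proved load-bearing for reproducing the physiological motions:

* *Costovertebral hinges.* Only the cranial edge pair of each rib end is
  fixed, so each rib can rotate about an oblique horizontal axis through
  its dorsal attachment, as at the costovertebral joint. Clamping the full
  end faces (available as `vertebral_clamp`) suppresses the rotation almost
  entirely.
* *Sternum and costal cartilage.* The ventral midline column is bone
  (sternum) and the ventral rib segments are compliant cartilage. The
  sternum anchors the ventral ends together (without it the ventral tips
  simply rise and the bucket-handle angle reverses sign); the cartilage
  decouples individual rib rotations enough for the activation gradient to
  differentiate them.
* *Caudal droop* of the arc toward the ventral midline, so elevation swings
  the ribs laterally (bucket handle) and ventrally (pump handle).
* *Fibre obliquity* at ±30° to the vertical in the sheet plane: external
  (caudoventral, inspiratory) versus internal (caudodorsal, expiratory).

**Diaphragm dome** (`make_dome()`): a spherical shell, apex cranial, with
meridional ("radial-pattern") fibres running from a passive central tendon
cap to the rim, and a small polar opening inside the cap avoiding
degenerate elements. Two optional asymmetries emulate the costal/crural
anatomy: dorsal meridians extended below the equator (longer, more vertical
crural fibres) and an anterior-flattening shear (`sternal_shear`)
reproducing the short, near-horizontal sternal fibres. The shear is the
feature that makes an activated dome move *ventrally* as well as caudally —
the clinically observed cupola path; a mirrored geometry mirrors the
motion, so the sign of the asymmetry is an anatomical input, not a fitted
constant.

What the toys do **not** contain: true rib geometry and articular
kinematics, the lungs and abdominal viscera (the pressures are prescribed,
not emergent), cervical accessory muscles, gravity, tissue viscosity, and
any subject-specific dimension. Passing the scenario checks therefore
demonstrates that the *mechanisms* — activation patterns plus fibre
architecture producing the documented motion signs and orderings — are
captured; it says nothing about patient-specific magnitudes, which is why
the scenarios assert only signs, orderings, and conservation properties.

## Activation fields and waveform

The spatial distributions are separable piecewise-linear ramps in
normalised anatomical coordinates, with extremes at the documented
locations: parasternal activation is 1 at the sternal edge and 0 at the
costochondral boundary; external intercostal activation peaks in the
dorsal part of the topmost interspace and decays ventrally (linearly) and
caudally; the internal field is its craniocaudal mirror. The caudal decay
uses an interspace weight `((K-k+1)/K)^power` with `power = 3` by default:
the electromyographic gradient is steep, and in the toy a weaker decay is
swamped by displacement carried from rib to rib through the sheet, which
would mask the documented "upper ribs rotate more" ordering. Quiet
breathing scales every field by `γ = 0.3`.

The activation time course has no closed form; it is a user-editable
breakpoint table. The shipped default is a rise–plateau–fall over a 5 s
breath (rise to 1 at 40 % of the cycle, relaxation complete at 90 %);
`ramp_waveform()` provides the linear 0→1 ramp natural for quasi-static
verification runs.

## Kinematic read-outs

Rib rotation is quantified by the best-fit (orthogonal Procrustes) rigid
rotation of per-rib landmark sets, decomposed in the fixed order
`R = Rz(ψ) Ry(θ) Rx(ω)`: θ about the anteroposterior axis is the
bucket-handle angle, ω about the transverse axis the pump-handle angle,
both right-handed ("anticlockwise positive"); landmarks are taken on the
right half of each rib so that elevation yields positive θ. Chest diameters
are projected extents (lateral x-extent, ventral y-extent) between stored
landmark pairs. For the diaphragm, the apex is the set of
reference-configuration nodes at maximal z; its mean caudal displacement
(positive caudally) is the dome-descent metric, and probe displacement
magnitudes are reported normalised against the first probe location.

## Problem sizes and tolerances used in the shipped checks

The verification problems run at deliberately modest resolution: the
uniaxial strip at 6×2×2 cells (864 elements), the rib toy at 12 arc cells
and 4 ribs (~1 400 elements), the dome at refinement 2 (960 elements), and
the combined quiet-breathing model at ~1 700 elements over 10 increments.
These sizes keep every scenario deterministic and in the tens of seconds
to a few minutes on one CPU while leaving the asserted signs and orderings
with clear margins. Tolerances mirror the physics: 1e-6 relative for
stress–energy consistency (limited by finite-difference truncation), 1 %
against the closed-form uniaxial solution, 0.5 % element volume error for
the incompressibility check, and 1e-3 of the element size for contact
penetration.

## Known limitations

* P1–P0 with perturbed-Lagrangian regularisation is the simplest workable
  mixed pair, not the best; thin muscle sheets still lock partially, so
  absolute compliances at default `stab` are underestimated.
* The force–length curves' non-smoothness limits Newton robustness near
  breakpoints; `stall_tol` works around it honestly (the accepted residuals
  are stated per increment) but a C¹ curve option would be cleaner.
* Contact assumes a rigid master and uses the closest face's normal for
  gap signing, adequate for smooth masters only.
* The activation fields are phenomenological ramps; only their extremes and
  monotonicity are anatomically anchored.
* Scenario magnitudes (angles in fractions of a degree at toy stiffness,
  dome descent of ~8–13 mm) are properties of the synthetic geometries and
  should not be compared quantitatively to any subject.
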