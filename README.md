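# respifem

Nonlinear finite elements for respiratory biomechanics in R.

Breathing is driven by muscle: the external and parasternal intercostals
rotate the ribs cranially and ventrally (the classical *bucket-handle* and
*pump-handle* motions that widen the chest), the internal intercostals
reverse them during active expiration, and the diaphragm dome descends
caudo-ventrally against the abdominal and pleural pressures. respifem
implements the continuum-mechanics machinery needed to simulate these
motions from muscle activation — rather than from prescribed displacements —
and is aimed at researchers building chest-wall and respiratory-system
models who want a transparent, fully scriptable, R-native implementation
with every numerical ingredient testable in isolation.

## The model

Muscle is an incompressible, transversely isotropic hyperelastic continuum
with an active Hill-type fibre. With C = FᵀF, J = det F, fibre direction N,
and the reduced invariants Ī₁ = J^(−2/3) tr C and
λ̄ = [J^(−2/3) C : (N⊗N)]^(1/2), the strain energy is

    U = c·exp(b(Ī₁ − 3)) + T₀ᴹ ∫₁^λ̄ f_PE(s) ds + T₀ᴹ·α(t)·γ ∫₁^λ̄ f_CE(s) ds

with f_PE(λ̄) = 2aA(λ̄−1)·exp(a(λ̄−1)²) for λ̄ > 1 (else 0) the passive
parallel element and f_CE the piecewise-linear active force–length curve
(separate intercostal and diaphragm calibrations, both peaking at 1 at unit
stretch, support [0.6, 1.2)); γ ∈ [0,1] is the spatial activation level and
α(t) its waveform. The second Piola–Kirchhoff stress S = −pC⁻¹ + ∂U/∂E is
taken as the *exact* energy gradient (verified against finite differences),
and incompressibility det C = 1 is enforced per element by a Lagrange
multiplier ξ with p = −2ξ (mixed u–p tetrahedra, P1–P0, perturbed-Lagrangian
regularised). Passive tissues (bone, cartilage, tendon) are Saint
Venant–Kirchhoff. The solver is incremental-static Newton with consistent
tangents, follower pressure loads evaluated on the deformed surface, and
frictionless rigid-master contact under the Karush–Kuhn–Tucker conditions
g ≥ 0, η ≤ 0, g·η = 0 via an active-set strategy.

Default muscle constants: T₀ᴹ = 0.3 MPa, c = 0.009348 MPa, b = 1.4939.
Units are mm–MPa–N (2 kPa = 2e-3 MPa); axes are +x left-lateral, +y
ventral, +z cranial.

All inputs are synthetic and generated in code: a fibre-aligned strip for
verification, a multi-rib cage toy with oblique intercostal sheets, sternum,
costal cartilage and costovertebral hinges, and a diaphragm dome with
meridional fibres radiating from a passive central tendon. Gmsh MSH v2.2
meshes can be read; VTU/VTK/MSH and a bit-exact internal format are
written. See the methods vignette (`vignettes/respifem-methods.Rmd`) for
the full account of model, discretisation and design decisions.

## Worked example

Material-point response of fully activated diaphragm muscle along
isochoric uniaxial states, followed by an activated clamped strip solved
with the FEM:

```r
library(respifem)

mp <- muscle_params(fl_curve = "diaphragm")
matpoint_table(mp, c(0.85, 0.95, 1.0, 1.05),
               act = activation_point(gamma = 1, alpha = 1))
#>   lam_f_bar   T_PE   T_CE    S11     S22
#> 1      0.85 0.0000 0.2336 0.1701 -0.0522
#> 2      0.95 0.0000 0.2787 0.1924 -0.0825
#> 3      1.00 0.0000 0.3000 0.2000 -0.1000
#> 4      1.05 0.1077 0.2917 0.2562 -0.1483
```

`T_CE` is the active nominal fibre stress T₀ᴹ·f_CE(λ̄)·α·γ: at optimal
length (λ̄ = 1) it equals the maximum nominal stress, 0.3 MPa; shortened or
lengthened fibres produce less. `T_PE` shows the passive element engaging
only beyond unit stretch. A strip of this muscle (6×2×2 mm, fibres axial,
both ends clamped axially) activated to γ = 1 then develops the full
contractile force over its 4 mm² cross-section:

```r
m <- make_strip(6, 2, 2, nx = 6, ny = 2, nz = 2, fiber_axis = "x")
sched <- activation_schedule(fields = list(uniform_field(m)),
                             waveform = ramp_waveform(), span = c(0, 1))
mod <- fe_model(m, list(muscle = mp),
                dirichlet = list(list(nodes = "x0", comps = 1),
                                 list(nodes = "x1", comps = 1),
                                 list(nodes = "y0", comps = 2),
                                 list(nodes = "z0", comps = 3)),
                activation = sched)
h <- newton_solve(mod, solve_config(n_increments = 4))
sum(reaction_forces(h, "x1")[, 1])
#> [1] 1.2
max(abs(h$increments[[4]]$detC - 1), na.rm = TRUE)
#> [1] 5e-05
range(h$increments[[4]]$p)
#> [1] -0.1 -0.1
```

The reaction 1.2 N is T₀ᴹ·f_CE(1)·A = 0.3 MPa × 4 mm²; element volumes are
preserved to 5e-5; and the hydrostatic pressure p = −2ξ = −0.1 MPa is the
value that annuls lateral stress in the active deviatoric state.

The physiological demonstrations run via the scenario API or the CLI
(`inst/cli/respifem.R`):

```r
res <- run_scenario(scenario_inspiratory_ribs())
res$checks
#> diameters_transverse  diameters_ap  theta_sign  omega_sign  rib_ordering
#>                 TRUE          TRUE        TRUE        TRUE          TRUE
```

— external intercostal + parasternal activation widens both chest
diameters, rotates the ribs cranially (θ, ω > 0) and rotates upper ribs
more than lower ones; `scenario_expiratory_ribs()`,
`scenario_diaphragm_isolated()` and `scenario_quiet_breathing()` cover the
expiratory mirror, the caudo-ventral dome descent, and the combined breath.

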