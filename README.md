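# headfem

Explicit finite-element simulation of head impact biomechanics in R, at
desk scale.

Blunt head impacts drive a pressure gradient across the brain —
compression at the impact site (*coup*), tension opposite it
(*contrecoup*) — plus deep shear and skull loading. Finite-element head
models resolve those fields and reduce them to the standard injury
measures. Research models are built on subject CT/MRI segmentations
with ~10⁶ elements; `headfem` replaces the anatomy with a parametric
layered stand-in (tri-axial ellipsoidal brain with labeled subregions,
CSF gap, skull shell, optional soft tissue) so the entire chain runs in
seconds on one CPU and every component is testable against analytic
oracles. It is aimed at injury-biomechanics students and method
developers who need a transparent, fully scriptable head model rather
than subject-specific biofidelity.

The package implements:

* **Parametric meshing** — deterministic radial-lattice tetrahedral
  meshes, watertight with exact shared-node tissue interfaces; quality
  audit (aspect ratio = circumradius/(3·inradius), dihedral angles,
  edge statistics); Laplacian and optimization-based smoothing with an
  inversion guard; VTK-legacy and Gmsh MSH output.
* **Tissue registry** — 11 components: elastic skull, cartilage and
  soft tissue; one-term Prony viscoelastic brain tissues,
  G(t) = G∞ + (G₀ − G∞)e^(−βt) (e.g. brainstem 0.0225/0.0045 table
  units, rate 80 s⁻¹), updated by the exact exponential deviatoric
  recursion with elastic volumetric response,
  K = 2G₀(1+ν)/(3(1−2ν)).
* **Surface-based CSF fluid cavity** — divergence-theorem volume of the
  closed CSF boundary, one uniform pressure p = K_f (V₀−V)/V₀, nodal
  forces as the exact gradient of the pressure–volume potential
  (conservative coupling), alongside a soft nearly-incompressible
  CSF-gap element response for local load transfer.
* **Explicit dynamics** — central-difference integration, lumped mass
  with density adjustment to a target head mass, nodal volumetric-strain
  averaging against near-incompressible locking, rigorous element-
  eigenvalue time-step control plus a cavity breathing-mode bound,
  penalty contact with rigid impactors, free-boundary impacts, energy
  and momentum audits.
* **Injury metrics** — HIC (windowed exhaustive search,
  HIC = max (t₂−t₁)[ā/g]^2.5), coup/contrecoup pressure extrema against
  the 234 / −186 kPa tolerance thresholds, peak brain von Mises stress,
  peak skull maximum-principal stress, and NDT (neutral-density-target)
  skull–brain relative motion with correlation scoring.

## Worked example: frontal impact replication

A cadaver-style frontal impact: free-floating head, 6 ms haversine
force pulse peaking at 7.4 kN applied to the frontal patch along a
45°-inclined axis.

```r
library(headfem)

mesh <- build_head_mesh(head_config())        # 8 mm edge, ~40k tets
probes <- place_pressure_probes(mesh)
history <- simulate_impact(mesh, nahum_case37(mesh), probes = probes)
print(history)
injury_report(history)
```

```
impact_history: 120 samples over 6.007 ms (dt = 1.36 us, 4403 steps)
  total mass 4.500 kg (density scale 2.008)
  peak impact force 7399 N, peak CG acceleration 1644 m/s^2
  p_coup           max    215.2 kPa  min   -8.756 kPa
  p_contrecoup     max    2.481 kPa  min   -130.8 kPa
  p_occipital_left max    2.611 kPa  min   -81.41 kPa
  p_occipital_right max  0.02094 kPa  min   -78.93 kPa
  p_posterior_fossa max 0.009493 kPa  min   -155.1 kPa
  peak brain von Mises 126.1 kPa, peak skull principal 7.247 MPa
  energy balance error 0.0286%
injury report
  HIC36 = 661 over (1.5, 4.5) ms
  coup             max    215.2 kPa @ 2.93 ms   min     -8.8 kPa @ 6.01 ms
  contrecoup       max      2.5 kPa @ 6.01 ms   min   -130.8 kPa @ 2.93 ms
  ...
  compression threshold (234 kPa) exceeded: FALSE
  tension threshold (-186 kPa) exceeded: FALSE
```

Reading the numbers: the head (density-adjusted to 4.5 kg) accelerates
at F/m ≈ 1.6 km/s², producing the classic coup-positive /
contrecoup-negative gradient; the coup peak is the inertial gradient
(≈ ±170 kPa at these conditions) plus a ~+40 kPa uniform pressurisation
of the sealed CSF cavity (the parametric head has no spinal CSF
outlet — see the vignette). Neither tolerance threshold is exceeded and
HIC stays under the 1000 safety limit. The energy audit closes to
0.03%.

The same run is available from a shell:

```sh
inst/exec/headfem simulate --preset nahum37-coarse --out out/
inst/exec/headfem metrics --out out/
```

which writes `history.csv` (channel/units header), `injury_report.json`,
`von_mises.vtk` and a `provenance.json` recording the unit
interpretation, time step, density scale and energy-balance error.

## Layout

```
R/            mesh, geometry, quality, smoothing, surfaces, materials,
              fluid cavity, dynamics, scenarios, injury metrics, I/O, CLI
src/          central-difference solver core (Rcpp)
tests/        testthat suite incl. oracle and acceptance checks
scripts/      acceptance.R
vignettes/    methods vignette (model, assumptions, limitations)
inst/exec/    headfem command-line entry point
```
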