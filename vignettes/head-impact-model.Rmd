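---
title: "A desk-scale finite-element head model for blunt impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale finite-element head model for blunt impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the model it implements: the
geometry, the constitutive laws, the CSF coupling, the solver numerics,
the load cases and the injury metrics, together with the design choices
that were genuinely open and the limitations a user should keep in mind.

## The problem

During a blunt head impact a pressure gradient develops across the
brain: compression at the impact site (coup) and tension at the
diametrically opposite site (contrecoup), with shear stresses deep in
the tissue. Finite-element head models resolve these fields and reduce
them to injury measures — peak intracranial pressure (ICP) against
tolerance thresholds, peak von Mises stress in the brain, peak principal
stress in the skull, the Head Injury Criterion (HIC) from the rigid-body
acceleration, and skull–brain relative motion at implanted marker
(neutral-density-target, NDT) columns. Research-grade models are built
on subject-specific CT/MRI segmentations with around a million elements;
this package replaces the anatomy with a parametric stand-in so that the
whole chain — meshing, constitutive behaviour, fluid–structure coupling,
explicit dynamics, metrics — runs in seconds to minutes on one CPU and
every piece is testable against analytic oracles.

## Parametric geometry

The head is modelled as nested tri-axial ellipsoidal shells: a brain
(default semi-axes 0.085/0.065/0.060 m, a 50th-percentile-male scale), a
CSF gap (3 mm), a skull shell (7 mm), and an optional outer soft-tissue
layer (off by default). Coordinates are x anterior, y left, z superior,
origin at the head centroid. Layer boundaries are ellipsoids with the
layer thickness added to each semi-axis; for thin layers this is within
a few percent of a true normal offset and keeps every interface an exact
shared-node sheet.

Meshing is a deterministic radial extrusion: a subdivided icosahedron
supplies the direction lattice, radial stations follow the target edge
length, and each triangular prism between consecutive shells is split
into three tetrahedra with a global-index diagonal rule that makes
neighbouring prisms agree, so the mesh is conforming and watertight by
construction. A structured lattice was preferred over Delaunay
refinement because Delaunay meshes are prone to slivers with small
dihedral angles; here element quality is controlled by the lattice and
can be audited (`quality_report()`: aspect ratio defined as
circumradius over three times the inradius, so the regular tetrahedron
scores exactly 1; dihedral angles; edge statistics). A seedable jitter
option perturbs interior nodes to exercise the two smoothers
(`laplacian_smooth()`, uniform weights with an inversion guard, and
`optimization_smooth()`, a local pattern search that maximises the worst
incident dihedral angle and therefore never lowers the global minimum).
Node insertion/deletion and local remeshing are not implemented; at the
coarse resolutions used here smoothing alone maintains validity.

Brain elements are sub-labelled by centroid: an outer `gray_matter`
shell, deep `white_matter` (inside 65% of the ellipsoidal radius), a
posterior-inferior `cerebellum` wedge standing in for the posterior
fossa, and optionally a `brainstem` core. These labels exist so that
pressure probes and NDT columns can be placed anatomically; they also
carry the distinct tissue materials.

With the default 8 mm edge the head has ~40k elements and ~7k nodes —
inside the 30–50k desk-scale band the package targets.

## Materials

The registry (`material_registry()`) carries eleven tissue components:
elastic skull/cartilage/soft tissue (density, Poisson ratio, Young's
modulus) and one-term Prony viscoelastic brain tissues with shear
relaxation

G(t) = G_inf + (G_0 − G_inf) e^(−beta t),

e.g. brainstem G_0 = 0.0225, G_inf = 0.0045 (table units), decay
constant 80. The printed table heads all moduli "GPa", but brain shear
moduli at GPa/MPa scale would be three orders of magnitude stiffer than
the constitutive literature the rows cite (tens of kPa), and decay
constants of 35–700 read as time constants in seconds would produce no
relaxation within a 6 ms impact. The default `units = "mixed"`
interpretation therefore reads elastic E in GPa, Prony G in MPa
(brainstem G_0 = 22.5 kPa) and the decay constant as a rate in 1/s;
`units = "literal"` keeps the printed reading. Every results file logs
the interpretation in force. The relaxation endpoints G(0) and
G(infinity) in table units are identical under both readings.

The bulk modulus of each brain tissue comes from its instantaneous
shear modulus and Poisson ratio, K = 2G_0(1+nu)/(3(1−2nu)); with
nu = 0.4996 this makes the tissues nearly incompressible, and the
volumetric response stays purely elastic (standard for shear-only Prony
relaxation). The incremental update uses the exact exponential
recursion for the deviatoric memory variable,

h_{n+1} = e^(−beta dt) h_n + 2 (G_0−G_inf) (1−e^(−beta dt))/(beta dt) Δe,

which is unconditionally stable, exact for strain paths that are linear
within a step, and is verified in the tests against a brute-force
hereditary-integral convolution to better than 1% on random 200-step
paths. Kinematics are small-strain with an optional corotational frame
(per-element polar decomposition); the impacts validated here produce
sub-percent strains outside the contact zone, and the corotational
option is off by default.

Densities follow the table; because the parametric head omits the face
and neck, integrating them over the bare head gives ~2.2 kg, and a
single global density scale adjusts the total to a realistic head mass
(default target 4.5 kg), mirroring the density-adjustment practice used
to hit average head weight. The scale is logged with every run.

## CSF: surface-based hydrostatic fluid cavity

The CSF gap is coupled as a hydrostatic fluid cavity: the closed
boundary surface of the `csf` region (two nested shells; Euler
characteristic 4) encloses the fluid volume, computed by the divergence
theorem. A single uniform pressure follows the linearised compressible
law p = K_f (V_0 − V)/V_0 (compression positive; no cavitation clamp by
default), and the nodal coupling forces are the exact gradient of the
pressure–volume potential, so fluid work equals −p dV to round-off and
the coupling is conservative — properties the tests check directly. The
default K_f is 2.19 GPa (water); a numerically softened option
(21.9 MPa) is available for larger stable steps, and the value in force
is logged in every results file.

One design point deserves emphasis. A *single* cavity pressure exerts
zero net force on the enclosed brain, so a cavity alone cannot transmit
the skull's deceleration to the brain — the brain would lag and close
the gap. The meshed CSF-gap elements therefore retain a soft
nearly-incompressible elastic response (default shear 1 kPa, bulk
21.9 MPa) that carries the local skull–brain load transfer, while the
cavity enforces global volume conservation of the CSF space. Probe
"intracranial pressure" is reported as the negative mean stress of the
probe's brain element (compression positive); the cavity pressure is
logged as its own channel.

## Explicit dynamics

The solver is a standard central-difference integrator over linear
(constant-strain) tetrahedra with a lumped mass matrix: internal forces
−B^T σ V per element, cavity forces, external loading, then
v_{n+1/2} = v_{n−1/2} + M^{−1} f dt and x_{n+1} = x_n + v_{n+1/2} dt.
The head floats free — no constraint on the six rigid-body degrees of
freedom, matching short-duration frontal impact practice where the neck
does not influence the brain pressure response; gravity is off.

Near-incompressible linear tetrahedra lock volumetrically. The solver
averages the volumetric strain over node-centred patches of brain
elements (restricted to the viscoelastic tissues so averaging never
crosses a material interface) before applying the volumetric stress; a
flag disables this for the patch test, which then recovers constant
stress and zero interior residuals to round-off.

The stable step combines three bounds: the altitude-over-wave-speed CFL
estimate (reported for diagnostics), a rigorous per-element frequency
bound (power iteration on the 12×12 element stiffness with the
element's own lumped mass — the elementwise eigenvalue theorem
guarantees the assembled system's highest frequency is below the
element maximum; the plain altitude estimate can overshoot the true
stability limit by ~40% on near-regular tetrahedra), and, when a cavity
is active, the cavity breathing mode 2/omega with
omega^2 = (K_f/V_0) Σ |dV/dx_i|^2 / m_i. The default safety factor is
0.8 and the default output interval 0.05 ms.

The energy audit accumulates external and internal work by the
trapezoidal rule, tracks the cavity by its exact potential, and reports
the balance (KE + internal + cavity − external work) relative to the
run's peak energy scale; the default frontal impact closes to better
than 0.1%, and the acceptance suite requires 2%. Impulse–momentum
closes to better than 1% (internal and cavity forces sum to zero
identically, so only the applied pulse changes momentum). Runs are
bitwise deterministic for a fixed configuration and seed.

Rigid impactors (hemisphere, or a flat circular face standing in for a
cylinder end) couple by penalty contact: force k·penetration along the
contact normal on each penetrating surface node, the resultant
decelerating the impactor, which is integrated by the same scheme.
Contact force is logged as the impact-force channel.

## Load cases and probes

`nahum_case37()` reproduces the classic cadaver frontal-impact
protocol: the anatomical plane inclined 45 degrees, so the load axis is
anterior–posterior-inferior at 45 degrees; free boundary; by default a
prescribed haversine force pulse F(t) = peak sin²(pi t/T) on the
frontal surface patch (area-consistent nodal weights), peak 7.4 kN —
just under the reported sub-7.5 kN experimental bound — and T = 6 ms,
the reported impulse duration. The impactor-contact alternative uses
the experimental 5.59 kg at 9.94 m/s. The 45-degree inclination is
applied to the load direction rather than re-meshing a rotated head;
under a free boundary the two are equivalent.

`place_pressure_probes()` returns five probes: coup at the anterior
pole (85% of the brain support radius, far enough inside to sit in a
well-shaped element), contrecoup at the posterior pole, bilateral
occipital probes at the posterior-lateral directions, and the
posterior-fossa (cerebellum) centroid. `place_ndt_columns()` places the
twelve NDT markers — an anterior column in the frontal lobe and a
posterior column in the parietal lobe on the right side, six markers
each at 10 mm vertical spacing (shrunk with a warning if a column would
leave the brain) — and attaches a skull reference node;
`relative_displacement()` differences marker and skull displacement in
the translation-following skull frame, and `ndt_correlation()` scores
simulated against reference series (Pearson). The exact experimental
NDT coordinates and skull fixed point are not published with the
protocol this mimics, so both are configurable; reproducing specific
experimental amplitudes is not claimed. `anvil_case()` builds the
hemispherical-anvil skull-loading cases (vertex / occipital / angled
frontal) used for peak contact force and skull principal stress.

## Injury metrics

HIC is computed by exhaustive search over sample pairs of the
resultant CG acceleration in g, max (t2−t1) [mean a]^2.5 with a window
cap of 36 ms by default (HIC15 available); an O(n²) brute-force oracle
checks it in the tests, and a constant 100 g for 10 ms gives exactly
1000, the conventional safety limit. Pressure extrema per probe are
classified against tolerance thresholds of 234 kPa (compression) and
−186 kPa (tension). Von Mises stress (peak over brain elements) and
maximum principal stress (peak over skull elements, closed-form
symmetric eigenvalue) are tracked over time in the solver;
`injury_report()` assembles everything, including a consistency check
that the brain von Mises peak time falls within half a pulse duration
of the impact-force peak.

## What the default replication shows — and does not

At the default resolution the frontal-impact replication produces the
expected response pattern: positive coup pressure, negative contrecoup
pressure, occipital and posterior-fossa troughs, CG acceleration under
the 2000 m/s² experimental bound, and a brain von Mises peak
synchronous with the force peak. The coup peak decomposes into an
antisymmetric coup/contrecoup gradient (the inertial term rho·a·x, here
about ±170 kPa) plus a uniform ~+40 kPa compression from cavity
pressurisation: the parametric head seals the CSF space completely,
whereas a real head relieves volume change through the foramen magnum
and spinal canal. Users comparing against gauge-pressure measurements
should keep that sealed-cavity offset in mind; it is visible directly
in the `cavity_pressure` channel.

The parametric geometry reproduces none of the anatomical detail that
shapes real intracranial fields — no falx/tentorium partitions, no
gyri, no ventricular system coupled to the subarachnoid space (the
ventricles exist only as an optional labelled tissue), no three-layer
skull sandwich, no facial skeleton. Passing tests demonstrate that the
numerical machinery is correct at desk scale, not that the model is
biofidelic for a specific subject.

## Numerical choices and degenerate inputs

Tolerances and tie-breaks worth knowing: element orientation is fixed
at construction (negative-volume tets are reoriented, zero-volume tets
rejected); smoothing rejects any move that would invert an incident
element; probe location falls back to the nearest brain element with
clipped barycentric coordinates if a point lies exactly on a face or
marginally outside; the HIC search clamps negative mean accelerations
to zero; `relaxation_modulus()` rejects negative times; the Lamé
conversion rejects nu ≥ 0.5; zero-variance series are rejected by the
correlation wrapper. Problem sizes used by the shipped tests: 16 mm
test meshes (~5k elements) for unit physics, the 8 mm default head
(~40k elements, ~3.3k steps for 6 ms) for the replication checks, and a
20 ms damped relaxation run on the 16 mm head for the hydrostatic-limit
oracle, chosen so the whole suite and the acceptance script run in a
few minutes on one CPU.
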