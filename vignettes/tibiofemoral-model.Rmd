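---
title: "A quasi-static multibody model of the tibiofemoral joint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-static multibody model of the tibiofemoral joint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

kneesim simulates the tibiofemoral compartment of the knee as two rigid
bodies — femur and tibia (the fibula treated as part of the tibia, the
patella omitted, as is usual for passive flexion) — coupled by fifteen
nonlinear tensile elements and by penalty contact between cartilage
surfaces.  The question the model answers is the classical passive-flexion
one: if an examiner imposes a flexion angle on the joint and nothing else,
where do the remaining five degrees of freedom settle, and which ligaments
carry the load there?

### Joint coordinates

Anatomical body frames are built from ten landmarks: the femoral frame has
its origin at the most distal mid-condylar point, Z along the mechanical
axis toward the hip centre, Y anterior (from the cross product of Z with
the posterior-condyle direction), X lateral for a right limb (medial for a
left limb, keeping the triad right-handed).  The tibial frame is analogous
with its origin between the tibial eminences and Z along the mechanical
axis from the ankle centre.

Relative pose is expressed in the clinical joint coordinate system with
one axis embedded in each bone: flexion–extension $\alpha$ about the
femoral X, internal–external rotation $\gamma$ about the tibial Z, and
abduction–adduction $\pi/2-\beta$ about the floating axis
$e_2 = e_3 \times e_1$ perpendicular to both.  The origin-to-origin vector
$H$ is resolved twice: as *joint translations* $S_1,S_2,S_3$ solving
$H = S_1 e_1 + S_2 e_2 + S_3 e_3$ in the (generally non-orthogonal) joint
basis, and as *clinical translations* $q_i = H \cdot e_i$.  Because $e_2$
is orthogonal to both embedded axes, the drawer translation satisfies
$S_2 = q_2$ identically, while $S_1 = q_1$ and $S_3 = q_3$ hold exactly
only at zero adduction.  This is the reading under which the drawer
identity holds for every pose, and it is asserted to $10^{-9}$ in the test
suite.  Internally all angles are radians; every file boundary and every
reported table uses degrees.

For a left limb the signs of adduction and internal rotation are inverted
during decomposition, so a mirrored left knee reports the same clinical
angles as its right-knee twin.

One convention had to be fixed by us: the flexion origin.  The model
defines $\alpha = 0$ as the full-extension pose produced by the
initialisation routine (below); an offset against any external convention
is a constant and drops out of the regression comparison.

### Ligament law

Each of the fifteen elements (double-bundle cruciates aACL/pACL and
aPCL/pPCL, double-bundle deep and oblique medial collaterals, superficial
MCL, LCL, anterolateral ligament, oblique and arcuate popliteal ligaments,
and the medial/lateral capsule elements) is a straight line between one
femoral and one tibial insertion; no wrapping is modelled.  Tension
follows the standard toe-then-linear law

$$F(L) = \begin{cases} 0 & \varepsilon < 0 \\
K_Q\,(L-L_0)^2 & 0 \le \varepsilon \le 2\varepsilon_1 \\
K_L\,\bigl(L - L_0(1+\varepsilon_1)\bigr) & \varepsilon > 2\varepsilon_1
\end{cases}, \qquad \varepsilon = \frac{L-L_0}{L_0}.$$

With the transition strain computed per element as
$\varepsilon_1 = K_L / (4 K_Q L_0)$, the quadratic and linear branches
join with matching value and slope at $\varepsilon = 2\varepsilon_1$, so
the force-elongation curve is C1 — a smooth toe-to-linear transition.  A
strict-literal variant that hands over already at $\varepsilon_1$ (and is
therefore discontinuous) is available behind the `strict_literal` flag for
comparison.

Slack lengths are not free parameters.  Following the usual
reference-strain construction, $L_0 = e\,L_e$, where $L_e$ is the
element's length with the knee at full extension and $e$ is a per-element
expansion constant: $e<1$ pre-tensions the element at extension, $e>1$
leaves it slack there.  Per-element $K_Q$, $K_L$ and $e$ ship as an
editable table (`synthetic_ligament_table()`, YAML-configurable); the
defaults are literature-typical bundle-level values (linear stiffnesses of
tens of N/mm, reference strains of a few percent) chosen so that the
extension-taut group (pACL, posterior MCL fibres, LCL, sMCL, popliteal and
capsular elements) and the flexion-recruited group (PCL bundles, anterior
deep-MCL fibres, ALL) reproduce the recruitment pattern expected of a
passive knee.  They are engineering defaults, not measurements.

### Contact

Cartilage-to-cartilage load transfer uses a penalty law on the penetration
depth $\delta$:

$$F_c = \begin{cases} 0 & \delta < 0 \\
k\,\delta^{\,p} - \dot\delta\, C\, h(\delta, \delta_c) & \delta \ge 0,
\end{cases}$$

with $k = 500$, $p = 1.5$, $\delta_c = 0.01$ mm and $C = 5$ kg/s; $h$ is a
unity-gain cubic smooth step over $[0, \delta_c]$, $\dot\delta$ the
separation rate (a closing contact adds damping force), and the total is
clamped at zero so contact never pulls.  Positive $\delta$ denotes interpenetration
(the sign convention carrying force).  The damping term contributes only in
dynamic-relaxation mode; quasi-static solves use $\dot\delta = 0$.

Penetration is evaluated per tibial-cartilage vertex against the femoral
cartilage surface (asymmetric by design: simple and convergent under
refinement).  Two aggregation modes are exposed because the original
rigid-body tooling this class of model descends from is ambiguous about
patch-versus-point application: the default `"area"` mode treats the
scalar law as a pressure and weights each vertex by its tributary area
(one third of its incident triangle area), making totals
resolution-robust; `"deepest"` applies a single resultant at the deepest
point.

### Numerical contact smoothing

A quasi-static solver that must drive residuals to $10^{-3}$ N cannot live
with the raw faceted distance field, and three choices in the contact
engine exist purely for smoothness.  They matter enough to document:

* **Phong-interpolated normals.**  The signed distance from a vertex to
  the surface is measured along the barycentric interpolation of vertex
  normals at the nearest point, not along the raw face normal, so force
  directions vary continuously across facet boundaries.
* **Soft-min blending.**  From the interior of a faceted surface the
  nearest-point map jumps across facet-bisector ridges.  All near-minimal
  candidate projections (within 15 µm of the minimum) are blended with
  exponential weights (length scale 3 µm), which removes those jumps at
  the cost of a bias far below the penetrations of interest.
* **Rim exclusion.**  Cartilage surfaces are open patches; a projection
  onto a boundary edge or vertex does not define a penetration (the
  surface simply ends there) and is discarded.  The synthetic condyle
  patches are generated oversized so their rims never approach a real
  contact.

Because the smoothed force field is the gradient of the closed-form
contact energy only to first order, the energy minimiser and the
force-balance root are distinct points a few micrometres apart.  The
package defines equilibrium by the force balance (the physically
meaningful statement) and uses energy descent for globalisation only.

### Equilibrium

At a prescribed flexion $\alpha$, the solver finds the remaining five
coordinates $u = (\gamma, \text{adduction}, S_1, S_2, S_3)$ at which the
generalized force (the net ligament-plus-contact wrench on the tibia
projected onto the coordinate tangents) vanishes to within the tolerance,
default $10^{-3}$ N and N·mm per component.  It is a damped Newton
iteration in two phases: first descent on the total potential energy
(ligament strain energy plus contact energy), then, once the residual is
moderate, a monotone Newton iteration on the force balance itself, with a
small bounded non-monotone escape for the rare residual-norm local
minimum.  The Jacobian is re-differenced every iteration (the active
contact set changes the stiffness), with a differencing step that shrinks
with the residual; a trust region bounds the worst-case cartilage-vertex
displacement per step so the cached active contact set stays valid.  The
energy trace of the descent phase is monotone; polish steps move
sub-micrometre distances.

### Initialisation at full extension

Slack lengths need the full-extension lengths $L_e$, and the reference
pose of a subject (or of the generator) is at mid flexion, so the knee is
first brought to full extension by continuation with the ligaments
inactive.  Contact alone leaves a frictionless joint unloaded and the
problem ill-posed (any separated pose is a trivial equilibrium), so this
mode closes the problem with a small axial compressive preload (30 N,
the examiner pressing the joint together) plus moderate centering springs
toward the neutral coordinates (500 N·mm/rad, 1 N/mm) on the motions
frictionless contact cannot stabilise.  These terms exist only during
initialisation; the passive-flexion solves use ligaments and contact
alone.  At $\alpha = 0$ every element's insertion-to-insertion length is
recorded as $L_e$ and $L_0 = e\,L_e$ is fixed thereafter.

### The passive-flexion rig

The experimental configuration is hinged-femur, moving-tibia: the femoral
origin and flexion axis are fixed to the ground, flexion is prescribed on
the femur (the examiner's hand — the constraint supplies whatever flexion
torque equilibrium requires), and the tibia is left fully free in the five
remaining coordinates.  We deliberately do not reproduce any partial
tibia-to-ground constraint: any such joint would suppress one of the five
dependent motions that the validation compares, so the quasi-static solve
carries the full stabilisation.  Four flexion cycles (≈7°→112°→7°) are
swept sample by sample with warm starts; a failed sample is retried with
halved continuation steps (down to 1/8) and flagged if still
unconverged.  Cycle-to-cycle variability comes from the commanded
profiles themselves (each cycle carries its own seeded, endpoint-safe
perturbation), never from solver noise.

## The synthetic knee

The generator stands in for image segmentation and emits the qualitative
features the model needs, with no claim of anatomical fidelity beyond
them:

* femoral condyles as swept-arc patches whose sagittal radius shrinks
  posteriorly (24→19 mm lateral, 25→20 mm medial, sigmoidal transition
  around 45° of arc) — the defining feature of condylar geometry;
* a concave-spherical medial plateau (30 mm dish) and a flat-to-saddle
  lateral plateau (gentle 120 mm sagittal trough), cartilage offset from
  coarser bone surfaces;
* ten landmarks placed so the body frames are exact;
* thirty insertion points placed near the condylar centre line — the
  near-isometric locus under passive flexion — with small
  anterior/posterior offsets that decide whether an element is taut in
  extension or recruited with flexion;
* four flexion cycles at 0.5° sampling with seeded perturbations, and a
  reference pose settled to 0.15 mm of contact at 15° of flexion.

Mesh resolutions (≈2.5k femoral and ≈2.7k tibial cartilage vertices)
were chosen so the sweep solves in tens of milliseconds per sample while
facet error stays below the penetrations of interest; the vertex counts,
cycle count and 0.5° sampling are the package's study conditions
throughout the tests and the acceptance script.

What the generator does *not* emulate: menisci, cartilage compliance
beyond the penalty law, ligament wrapping, anatomically measured insertion
scatter, soft-tissue viscoelasticity, and measurement noise of a motion
capture rig.  A passing validation on this fixture therefore demonstrates
the correctness and internal consistency of the machinery — frames,
constitutive laws, equilibrium, parameterisation and regression — not
fidelity to any particular cadaver.

## Validation pipeline

Trajectories (simulated or experimental, same CSV schema) are
parameterised by flexion: each cycle is split at peak flexion into rising
and falling limbs, each limb linearly resampled onto a uniform grid, and
a median-absolute-deviation screen (threshold 5, configurable, with a
0.5 mm/degree gross-error floor so the screen stays active on noise-free
traces whose MAD is zero) stands in for the visual removal of spurious
samples.  Cycles are averaged
pointwise, and each dependent motion of the experimental data is
regressed on its simulated counterpart, $y = b_0 + b_1 x$, over the
truncated (7–90°) and full (7–112°) flexion ranges.  Reported per cell:
slope, intercept, RMSE, adjusted $R^2$, the two-sided slope p-value and
Pearson's $r$ (for a simple regression the slope t-test, the model F-test
and the correlation test coincide, so the choice of "the" p-value is
immaterial).  The regression keeps the experimental-on-simulated
orientation; a verbose flag reports the reverse fit too.

## Known limitations

* Ligaments are straight lines; elements that wrap bone in deep flexion
  (sMCL in particular) are stiffer in the model than in tissue.
* The anterior ACL bundle of the synthetic knee shortens monotonically
  with flexion, so its mid-flexion engagement band is not reproduced; the
  posterior bundles of both cruciates, which the recruitment checks
  target, behave as expected.
* In a narrow mid-flexion band the energy landscape is bistable in
  internal rotation by a fraction of a degree; rising and falling sweeps
  can settle into either well (each a converged equilibrium).  The drawer
  translation is insensitive to this; the checks therefore assert
  history-freeness on coordinates, at probe angles, and no-hysteresis on
  the drawer trace.
* The dynamic-relaxation mode is a damped pseudo-dynamic settle with
  nominal inertias (a preconditioner for stiff or distant starts, with
  the contact damping term active), not a dynamics engine: gait- or
  landing-speed phenomena are out of scope.
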