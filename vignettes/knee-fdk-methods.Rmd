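---
title: "Methods: force-dependent kinematics simulation of the tibiofemoral joint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-dependent kinematics simulation of the tibiofemoral joint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`kneefdk` simulates the loaded knee quasi-statically over an activity
cycle. One coordinate — tibiofemoral flexion — is prescribed per frame;
the ten remaining joint coordinates (5 tibiofemoral: ab/adduction,
internal rotation, three translations; 5 patellofemoral) are *secondary*:
they are searched until the generalized force conjugate to each vanishes
below a threshold (force-dependent kinematics, FDK). The passive
structures are 22 straight-line ligament bundles with a piecewise
quadratic/linear force–strain law, and five elastic-foundation contact
pairs between triangulated cartilage and meniscus surfaces. Muscle
tensions are re-solved inside every residual evaluation by a
static-optimization problem with a cubic cost, so the secondary positions
are genuinely force-dependent. The headline output is the tibiofemoral
contact force (TFCF) — total, medial and lateral compartment — in units
of body weight (BW) on a 101-point normalized cycle.

## Constitutive models

**Ligaments.** A bundle with stiffness $k$ (N/strain), linear strain
limit $\varepsilon_l$ and engineering strain $\varepsilon$ carries

$$f(\varepsilon)=\begin{cases}0 & \varepsilon<0\\
\tfrac14 k\varepsilon^2/\varepsilon_l & 0\le\varepsilon\le 2\varepsilon_l\\
k(\varepsilon-\varepsilon_l) & \varepsilon>2\varepsilon_l\end{cases}$$

tension-only, along the origin–insertion line. The two branches meet at
$2\varepsilon_l$ with value $k\varepsilon_l$ and common slope $k$ (C1).
Slack lengths are calibrated so each bundle attains its tabulated
reference strain $\varepsilon_r$ at full extension:
$L_0=L_{\text{ext}}/(1+\varepsilon_r)$. The tabulated
$(k,\varepsilon_r)$ set covers 10 ligaments in 22 bundles.
$\varepsilon_l$ is not tabulated anywhere we could verify; we default to
0.03 for every bundle (the customary value for this law) and expose it
per bundle. Consequence worth knowing: the bundles with positive
$\varepsilon_r$ (cruciates, collaterals, patellofemoral ligaments) are
taut at full extension, which pre-compresses the unloaded joint by
roughly 0.8–0.9 BW in the default fixture. That is a property of the
stated parameter table, not a bug.

**Contact.** Each cartilage/meniscus pair is an elastic foundation: for
slave vertex $i$ with tributary area $A_i$ (one third of incident
triangle area) penetrating the master surface to depth $d_i$,
$F_i = PM\,A_i\,d_i$, compressive only, along the slave vertex normal,
with the pressure module

$$PM=\left[\frac{(1+v_1)(1-2v_1)}{1-v_1}\frac{h_1}{E_1}+
\frac{(1+v_2)(1-2v_2)}{1-v_2}\frac{h_2}{E_2}\right]^{-1}.$$

Depth is measured by casting a ray from the slave vertex along its
inward normal against the femoral master surface (the femoral cartilage
participates in all five pairs, so it is always the master). A signed
closest-point alternative (`method = "project"`) exists because ray
depth is discontinuous at grazing incidence; the default fixture instead
shapes its surfaces so no slave normal meets the master tangentially
(see *Numerical choices*). Friction is not modeled. Menisci are fixed to
the tibia; their loads count toward the tibiofemoral compartment totals.

**Muscles.** Maximum isometric force is $F_0=\mu\,\mathrm{Vol}_0/L_{f0}$
with $\mu = 27\ \mathrm{N/cm^2}$. Recruitment minimizes
$\sum_i V_i (f_i^M/N_i)^3$ subject to the driven-coordinate equilibrium
$Cf=r$ and $f^M\ge 0$, by a primal log-barrier interior-point method
(KKT tolerance $10^{-8}$; the cubic gradient is continuous at zero so no
smoothing is needed). Reaction columns are unbounded and unweighted.
Ligament and contact forces are position-dependent *applied* loads: they
enter $r$, not $f$. In the default knee construct the constraint system
is the single flexion-moment equation; the eight muscle units (4
quadriceps via the patella, 2 hamstrings, 2 gastrocnemius heads) span
both moment signs, so the equation is feasible for either demand.

## The FDK search

The residual is assembled by virtual work: all loads on the tibia and
patella are reduced to body wrenches and dotted with the body twists
$\partial(\text{pose})/\partial\alpha_j$ (central differences of the
kinematic map). Rotational coordinates are stated in degrees but their
conjugate forces are expressed per radian, i.e. as physical moments. The
convergence threshold is 1 N on force coordinates; for moment
coordinates the stated threshold is converted through a characteristic
lever (default 10 mm, i.e. 10 N mm) — the source threshold is stated in
newtons only, so this conversion is our documented, configurable choice.

The search is a damped Newton iteration on the scaled residual with a
central finite-difference Jacobian (step $10^{-3}$ mm or deg),
per-coordinate trust bounds, a line-searched Cauchy fallback, and one
pragmatic addition: if no direction reduces the residual, the Jacobian
step is coarsened (up to $10\times$) before giving up, because the
residual is only piecewise-smooth across mesh facets. Warm starts come
from the previous frame; `tracked_patellar_alpha()` can seed the
patellar coordinates along an expected trochlear track, but with the
default geometry the rigid tendon plus the concentric trochlea nearly
lock the patellar attitude to the tibia and the plain warm start
suffices (`patellar_tracking = 0`).

## The 11-DOF joint and the rigid patellar tendon

Axes: x anterior, y medial (the transepicondylar/flexion axis), z
superior; all body frames coincide with the global frame at the
full-extension reference; rotation order flexion → ab/adduction →
internal rotation. The patellar tendon is rigid and is *eliminated*, not
penalized: the five patellofemoral coordinates are two tangential
displacements of the tendon direction about its tibial insertion plus
three patellar rotations, so tendon length is constant by construction
and the tendon constraint force drops out of every virtual-work term.
This keeps the patella parameterized relative to the tibia — which also
keeps the quadriceps' extensor moment arm inside the muscle columns of
the recruitment equation rather than hidden in the passive terms. A
14,700 N/strain elastic tendon is the documented alternative the
elimination replaces; the residual checker
`patellar_tendon_residual()` verifies any pose against the rigid length.

## The synthetic world

No measured geometry or motion data are distributed with the package;
the fixture module generates a *stated world*:

* **Geometry.** Spherical femoral condyles (radii 22/21 mm, centers ±22
  mm on the flexion axis) articulating with dished tibial cartilage
  (35 mm dish radius, 0.2 mm reference clearance), meniscal rings
  conformal to the condyle over an inner band and falling away outside
  it, and a patellar cartilage concentric with the anterior condylar
  surfaces (0.3 mm clearance). Because the condyles are spheres centered
  on the flexion axis, flexion leaves the tibiofemoral contact geometry
  invariant — deliberately benign and controllable. Ligament attachments
  are plausible anatomical positions stated in the fixture (the
  patellofemoral ligaments attach on the epicondylar axis and are hence
  near-isometric, as anatomy has it); they are config data, not claimed
  reproductions of any cadaveric digitization.
* **Subject.** 73.4 kg, 1.78 m (a cohort-mean adult).
* **Activities.** Five cycles (walking 1.1 s, stair ascent 1.4 s, stair
  descent 1.3 s, sit-to-stand 1.8 s, stand-to-sit 1.9 s) stated as
  smooth periodic bump/logistic waveforms for flexion and shank
  inclination, a single-leg vertical GRF shape rescaled so its cycle
  mean is exactly half body weight (two-feet impulse balance holds by
  construction), and ground-reaction *lever* waveforms about the knee
  (mm) with literature-typical magnitudes (peak sagittal knee moments ≈
  40 N m walking, ≈ 60 N m stairs, ≈ 35–45 N m transfers; frontal lever
  ≈ 13–17 mm medial). The center of pressure is placed by inverting the
  moment balance so the inverse-dynamics stage reproduces exactly those
  levers; marker trajectories are the ground-truth kinematics plus
  seeded isotropic Gaussian noise (default σ = 1 mm).

What a green end-to-end test establishes: the pipeline converges on all
frames, conserves compartment decompositions, and reproduces the
qualitative load patterns (two stance peaks in gait with the first
larger; single transfer peak; medial share ≈ 55–70%). What it does not
establish: agreement with any in vivo measurement — peak magnitudes in
this world run ≈ 1 BW above the published in vivo range because the
fixture's quadriceps lever (~34 mm) is below anatomical values and the
stated ligament pretension adds a baseline compression. Those numbers
depend on undeposited participant data and are explicitly out of reach
at desk scale.

## Numerical choices

* STL welding tolerance $10^{-6}$ mm; zero-area faces dropped at
  construction.
* Triharmonic ($r^3$) RBF kernel with a first-order polynomial term for
  bone morphing: landmarks are interpolated exactly and affine motions
  are reproduced exactly; the system matrix is rejected as
  ill-conditioned for coplanar or duplicate landmarks.
* The femoral master surface extends 170° from its cap axis. The contact
  direction sweeps ~40°–130° off that axis between extension and deep
  flexion and the meniscus rim adds ~30° more; a shorter cap lets slave
  rays fall off the master edge, which makes the contact force — and
  therefore the FDK residual — discontinuous. The meniscus top is
  conformal to the condyle only over an inner band (to 12 mm radius) and
  flat outside it, so no slave normal meets the sphere at grazing
  incidence.
* Recruitment infeasibility is diagnosed by a bounded least-squares
  fit naming the most-violated equation; a singular KKT system (e.g.
  redundant free columns) is reported as a rank error only when the
  problem is otherwise feasible.
* The sphere-on-plane oracle $F = PM\,\pi R\,\delta^2$ is the
  small-$\delta/R$ limit of the foundation integral (relative truncation
  $\approx \delta/3R$); tests probe it where that truncation is well
  below their tolerance.
* Determinism: all fixture randomness flows through one integer seed;
  the solvers contain no randomness, so identical inputs give
  bit-identical outputs.

## Known limitations

Linear-elastic cartilage only; no meniscal motion relative to the tibia;
no muscle activation dynamics or wrapping; straight-line ligaments
without wrapping; the lower-limb construct reduces the full-body model
(proximal muscle origins are femur-fixed; hip and ankle are represented
only through the intersegmental load). Rotational inertia of the shank
is neglected in the dynamic mode of the intersegmental load
(quasi-static is the default). The 55-marker full-body tracking stage is
reduced to per-body least-squares (Kabsch) fits of femur and tibia
marker clusters.
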