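---
title: "Model and methods: a coupled lattice-Boltzmann / spring-network cell in a constriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a cell is pushed through a microfluidic constriction narrower than its
own diameter, the time it needs to squeeze in (the *entry time*) and the time
it needs to slide through and exit (the *transit time*) encode its
viscoelastic properties and its surface friction against the channel walls.
Devices built on this principle — suspended microchannel resonators with a
6 µm × 15 µm × 50 µm constriction and a 45° tapered entrance — are used to
phenotype circulating tumor cells, whose deformability governs whether they
lodge in capillaries. `cellsqueeze` implements the forward model of this
experiment (a deformable spring-network cell two-way coupled to a
lattice-Boltzmann fluid, with wall repulsion and kinetic wall friction) and
the inverse problem: a genetic-algorithm identification of the membrane
moduli and the friction coefficient from measured entry/transit times.

## Unit system

Everything internal runs in micrometres, microseconds and picograms. This
triple is self-consistent with every printed constant of the problem
domain: the derived force unit is the nanonewton
(pg µm/µs² = 10⁻⁹ N), the dynamic-viscosity unit is the
millipascal-second, the density 1006 kg/m³ becomes 1.006 pg/µm³, and a
fluid-coupling coefficient quoted in nN·s/m is numerically identical in
pg/µs. The five elastic moduli, the membrane viscosity and the friction
coefficient are dimensionless numbers of order 0.1–10 in this system; the
identification bounds (`ga_bounds()`) are [10⁻⁴, 10] for the stretching,
bending and local-area moduli, [0.1, 10] for the global-area, volume and
membrane-viscosity coefficients, and [10⁻⁴, 1] for the friction
coefficient.

## The membrane model

The cell surface is a closed, outward-oriented triangulation (393 nodes for
the production 6.5 µm cell; `build_sphere_mesh()` reaches arbitrary counts
by midpoint-subdividing an icosahedron and collapsing the shortest edges
under a manifold-preserving link condition, then relaxing tangentially on
the sphere). Each node obeys Newton's second law with uniform nodal mass
$m_j = \rho V_0 / N$, integrated by velocity Verlet. Six Kelvin–Voigt
force terms act on the nodes:

* **Stretching** — each edge is a nonlinear spring,
  $F = k_s\,\kappa(\lambda)\,(L - L_0)/L_0$ with stretch
  $\lambda = L/L_0$ and the neo-Hookean factor
  $\kappa(\lambda) = (\lambda^{1/2} + \lambda^{-5/2})/(\lambda + \lambda^{-3})$,
  equal to one at rest and reciprocal-symmetric
  ($\kappa(\lambda) = \kappa(1/\lambda)$).
* **Bending** — each edge is a hinge with rest dihedral $\theta_0$
  measured between the outward-oriented adjacent triangles (flat pairs give
  $\pi$; the convex/concave branch is disambiguated by which side of the
  first triangle's plane the opposite vertex lies on). A restoring load of
  magnitude $k_b (\theta - \theta_0)/\theta_0$ acts along each triangle's
  normal. Bending laws of this family specify a load per triangle without
  fixing which vertex receives it; we apply it at the apex vertex opposite
  the shared edge of each triangle and compensate with $-\tfrac12$ of the sum on the two shared
  vertices, which makes every hinge momentum-free — a requirement for a
  free-floating cell.
* **Local area** — per triangle, forces along the vertex→centroid
  directions scaled by $(S_{ABC}-S^0_{ABC})/(t_a^2+t_b^2+t_c^2)$. We
  orient the force *toward* the centroid when the triangle has grown; the
  opposite orientation would amplify area deviations rather than restore
  them.
* **Global area and volume** — the same geometric carriers scaled by the
  global relative deviations $(S-S^0)/S^0$ and $(V-V^0)/V^0$, the volume
  term acting along outward triangle normals weighted by triangle area.
  Because each triangle's three vertex→centroid vectors sum to zero and
  the area-weighted normals of a closed mesh sum to zero, all internal
  elastic terms conserve linear momentum exactly (tested to 10⁻⁹
  relative).
* **Membrane viscosity** — a Newtonian damper per edge. Damping the
  projection of the *absolute* nodal velocity on the edge is one common
  writing of this term, but it is not Galilean-invariant: a rigidly
  advected cell would feel spurious drag. The default therefore damps the
  *edge-relative* velocity $(v_A - v_B)\cdot\hat p$ with
  equal-and-opposite forces (`viscous_mode = "relative"`); the absolute
  form remains available as `viscous_mode = "literal"` for comparison.

## Fluid and coupling

The fluid is a D3Q19 lattice-BGK solver with the standard second-order
equilibrium and Guo forcing — the de-facto standard, second-order
accurate choices. Walls use halfway bounce-back on a voxelized channel mask; the
45° taper is voxelized at the grid resolution. The relaxation time comes
from $\nu_\text{lattice} = c_s^2(\tau - \tfrac12)$. Driving mimics the
experiment's constant pressure drop: a constant body force calibrated so
the *blank-channel* steady flow rate matches the target (linearity of
Stokes flow makes the calibration converge in a few proportional updates;
we verify doubling the target doubles the force to within 2% in the
Re ≪ 1 regime). The force is then held fixed while the cell, an extra
hydrodynamic resistance, slows the flow — exactly as a constant ΔP would
behave.

Cell and fluid exchange momentum through dissipative point drag:
$F_j = \xi\,(u - v_j)$ with $u$ trilinearly interpolated at the node. A
sign worth spelling out: written as $\xi(v-u)$ the same expression would
pump energy into the membrane instead of draining it; only $\xi(u-v)$ is
a drag, so that is the default, with the reversed sign behind a flag for
comparison experiments. The per-node coefficient scales from a
calibrated reference sphere (radius 4 µm, 393 nodes) as
$\xi = (n_\text{ref}/n)\sqrt{S/S_\text{ref}}\,\xi_\text{ref}$, with
$\xi_\text{ref}$ linearly interpolated in viscosity between the calibrated
fluids (0.922 nN·s/m for the 0.785 mPa·s culture medium). The
back-reaction deposits the exact opposite impulse onto the fluid through
the same trilinear stencil, once per Verlet half-kick, so the coupled
system conserves momentum to 10⁻⁹ relative over thousands of steps (the
periodic-box test in the suite).

Within one membrane step the fluid field is frozen; the lattice advances
every `n_sub` membrane steps with step `n_sub * dt`. At the quasi-steady,
low-Mach conditions of these runs (lattice velocities ≲ 0.1) this
subcycling is far below the fluid's own time scales.

## Walls

Node–wall interaction uses the analytic signed distance to the channel's
wall patches (two piecewise-linear width-profile side walls covering the
straight sections and tapers, two flat depth walls) rather than a
discretized wall point cloud — exact and mesh-independent. Repulsion
$a\,n/d^{\,n+1}$ (defaults $a = 10^{-4}$, $n = 1.2$) activates strictly
below $d_\text{cut} = 0.1$ µm; penetrating nodes are clamped to a minimum
distance and counted as penetration events. Kinetic friction has magnitude
exactly $\mu_f$ times the local repulsion and by default opposes the
full nodal velocity (a wall-tangential option is provided); a 10⁻⁶ µm/µs
dead-band regularizes the direction at rest — the model is kinetic
friction only, with no static threshold.

## Scenarios

**Channel passage.** The flow is pre-converged in the blank channel, the
cell is placed on the centreline with its leading edge 1 µm short of the
taper-entrance plane (all nodes clear of $d_\text{cut}$), then released.
The entry clock starts when the leading edge crosses the taper-entrance
plane — the only geometrically unambiguous upstream event; the notion of
a cell *completely entering* fixes the end of the entry phase but not its
start — and entry ends when the trailing edge crosses the constriction-entrance
plane; transit ends when the trailing edge crosses the exit plane.
Crossings are linearly interpolated from the recorded edge trajectories,
making the times insensitive to the output cadence at first order. A run
with no trailing-edge progress over a configurable horizon is flagged
`stalled` rather than erroring, because a cell wedged at the entrance is a
physically meaningful outcome (it is how an over-stiff or viscosity-free
membrane can behave at low flow rates). Replaying a configuration is
bit-identical: the solver contains no randomness.

**Optical-tweezers stretch.** Opposite loads $\pm F/N_c$ are applied to
the nodes within a polar cap covering a fraction (default 0.1, matching
the ~2 µm bead contact on a ~8 µm red blood cell) of the axial extent at
each end, and the membrane relaxes to quasi-static equilibrium under a
light ambient drag ($\gamma = m_j/2$ per node; heavy overdamping biases
the converged shape and slows convergence). Axial and transverse diameters
come from extremal node coordinates. This scenario drives the red-blood-cell
validation route of the identification method; `biconcave_rbc_mesh()`
provides the classical biconcave discoid, and any external tessellation
can be loaded through the plain-text mesh format instead.

## Channel geometry variants

The production channel (`model3`) is the constriction part of the full
device: a straight upstream section, the 45° taper, the
6 × 15 × 50 µm³ bore and a mirrored expansion. `model1` adds the long
far-field sections (whose exact dimensions barely affect the constriction
flow; defaults are configurable), `model2` is intermediate, and `model4` keeps
only the tapered entry and the first fifth of the bore. The axial ends are
periodic, which is why variant masks keep equal entrance and exit widths;
the grid-sensitivity helper `grid_study()` compares steady profiles at a
cross-section of the wide section at spacings 1.5/1.25/1.0 µm, whose
transverse dimensions (30 and 15 µm) voxelize identically at all three
spacings.

## Parameter identification

Chromosomes are 128-bit binary fractions per parameter, decoded affinely
onto the bounds. Each iteration evaluates a budget of distinct candidate
sets (~400 at production scale) generated by tournament selection
(size 2), per-parameter single-point crossover and per-bit mutation, plus
the 20 best sets of the previous iteration injected unchanged; elitism
makes the best-error history non-increasing. The description "performed
for probabilities of higher than 0.8" is read literally: a uniform draw
above 0.8 triggers the operator, i.e. a rate of 0.2 per parameter
(crossover) and per bit (mutation); both thresholds are configurable. The
run stops below an error threshold or after 20 iterations without
improvement. Crashed or stalled simulations score +∞ and stay in the books, so
unstable corners of the parameter box are searched around instead of
aborting the identification. Evaluations are
cached by decoded parameter set, so evaluation order cannot change the
result, and a fixed seed reproduces a run bit-for-bit.

Identification of a cancer cell is two-staged, following the physics:
entry is dominated by deformability while transit feels both deformability
and wall friction. Stage 1 searches the six viscoelastic parameters with
friction off, minimising the summed relative entry-time error over the
measured flow rates; stage 2 freezes those parameters and searches the
friction coefficient separately per flow rate against that flow rate's
relative transit-time error (the number of wall-contact nodes differs
between flow rates, which is why a single global $\mu_f$ is not used).
Error thresholds for the two stages default to 0.05; the stretch-error
route uses a stop threshold of 1, the `ga_config()` default.

## The synthetic fixture

`fixture_scenario()` defines the desk-scale closed-loop testbed: a 162-node
cell of radius 3 µm passing a 3 × 7 × 10 µm³ constriction (squeeze ratio
2.0, matching the production 13/6) in a 10 µm-wide channel, at flow rates
of 10 and 20 µL/h, with membrane step 0.02 µs and fluid subcycling 10.
Reduced resolution, not reduced physics: every force term of the model is
active. The generating parameters
($k_s = 0.5$, $k_b = 0.8$, $k_{al} = 0.05$, $k_{ag} = 0.9$, $k_V = 3$,
$k_{visc} = 1.5$, $\mu_f = 0.45$) were chosen once, for physical rather
than numerical reasons: moduli of order the Table-scale values; a volume
modulus strong enough that the squeezed cell stays within 2% of its rest
volume; and a friction coefficient at which transit is visibly
friction-dominated (µ_f spans roughly ±40% of the transit time over its
bounds) while entry remains deformation/advection-dominated — the same
asymmetry the constriction assay exploits and the two-stage
identification assumes. The fixture's flow rates give Reynolds numbers of 2–5, above the
production device's ≲1 but still laminar; this is the price of passages
that integrate in about a second on one core.

What passing closed-loop tests on this fixture shows — and what it does
not: the GA machinery, the error functions, the two-stage logic and the
full force stack work end-to-end, and the recovered parameter sets
reproduce the generating passage times within 5%. Entry time at desk scale
is only weakly sensitive to the individual moduli (the inverse problem is
under-determined there, as it is at production scale: many parameter sets
yield the same times), so recovery of *times* is the tested contract, not
recovery of each *parameter value*. Real data add measurement noise,
cell-to-cell variability and adhesion effects that the model deliberately
omits.

## Numerical choices and limitations

* Membrane step 0.01 µs at production parameters (0.02 µs on the
  fixture); the hard limit is wall-contact stiffness (the repulsion's
  $d^{-2.2}$ gradient), not the springs. Very large membrane-viscosity
  values (≳6 at the fixture step) destabilize the explicit damper; such
  candidates crash and score +∞ in identification, shrinking the
  effectively searchable corner of the parameter box; the run history
  records how often this happens.
* BGK with $\tau$ derived from viscosity; fluid steps chosen so
  $\tau \in [0.55, 1]$. Lattice Mach stays below 0.1 in every scenario.
* Degenerate triangles are flagged during force evaluation and abort the
  run; penetration events (negative wall distance) are clamped and
  counted, not silently ignored.
* Ties in the wall-distance query resolve to the first patch in a fixed
  order (upper side, lower side, bottom, top).
* The entry-time clock start (taper contact) and the cell's initial
  placement are configurable: both are modelling conventions, not
  physical constants.
* No nucleus, no receptor–ligand adhesion, no remeshing, no thermal
  fluctuations; cytoplasmic and nuclear mechanics are lumped into the
  membrane parameters.

## Reproducing the headline numbers

The acceptance script (`scripts/acceptance.R`) recomputes the package's
worked-example quantity from scratch; the test suite recomputes the
flow-rate scaling (45.6 / 22.8 µL/h from the 38 µL/h blank at 1.5 psi),
the identification errors from the measured and best-fit passage times
of the lung-cancer-cell constriction experiment, the
coupling-coefficient calibration values, and the desk-scale physics checks
(rest-state force cancellation, Poiseuille within 2%, momentum
conservation, grid-spacing agreement within 5%, the closed-loop recovery
and the friction/viscosity ablation directions). Full-scale passage
reproduction (entry times of order 10⁴ µs on a 393-node cell, ≳10⁶
coupled steps) is a cluster-scale computation and is deliberately out of
the test suite; the machinery for it is the same `run_channel_passage()`
at `channel_geometry("model3")` defaults.
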