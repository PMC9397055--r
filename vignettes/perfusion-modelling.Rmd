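---
title: "Geometry-based perfusion modelling of printed bone scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-based perfusion modelling of printed bone scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Extrusion-printed bone tissue-engineering scaffolds are lattices of fused
polymer filaments. When such a scaffold is perfused with blood — in a
bioreactor or after implantation — the flow through its pore network
determines whether cells survive on it: the flow must deliver nutrients
(sufficient permeability, low pressure drop) while the wall shear stress
(WSS) it exerts on the filament surfaces must stay below roughly 30 mPa,
the level above which shear is regarded as detrimental to cell
proliferation and differentiation. `scaffoldflow` predicts these
haemodynamic quantities directly from the printing parameters, so designs
can be ranked before anything is printed.

The pipeline is: parametric solid construction → geometric
characterisation → voxelization → steady incompressible flow solve →
pressure drop, Darcy permeability, interstitial Reynolds number, WSS field
and the sub-threshold viable surface fraction, swept over inlet blood-flow
velocities of 1–9 mm/s.

## Scaffold geometry

Two design families are modelled.

**Rectangular 0/90 lay-down.** Layers of parallel cylindrical filaments
(diameter $d_f$) are stacked with each layer rotated 90° from the last.
Pore size $d$ is the clear edge-to-edge spacing between adjacent filaments
in a layer, so the centre-to-centre spacing is $d + d_f$ and a layer of
width $W$ holds $\lfloor W/(d+d_f)\rfloor + 1$ filaments, centred on the
footprint. Consecutive layers are spaced by the layer pitch $p \le d_f$
along the build direction, so they interpenetrate by $d_f - p$ and fuse
into a single body; the fused stack is centred in the bounding height and
trimmed flush. The reference designs use $d_f = 0.33$ mm, $p = 0.31$ mm,
ten layers in a 20 × 20 × 3.1 mm envelope, and pore sizes of 0.300, 0.350
or 0.45 mm.

**Graded elliptical rings.** The anatomically-motivated design places the
same filament stack on an elliptical footprint (31 × 26.7 mm) divided into
six concentric annuli; the local filament spacing in ring $r$ is
`pore_sizes[r]` $+\,d_f$, with the pore size increasing strictly from the
innermost (476 µm) to the outermost ring (979 µm). The published design
does not state the ring radii, so annulus boundaries default to equal
fractions of the semi-axes; filament positions march outward from a
central filament, each gap set by the ring containing the current filament
centre. Filaments are cut flush with the elliptical boundary. This is a
parametric emulation of the published CAD, not a reproduction of its exact
anatomical outline.

Porosity is reported as the void fraction of the bounding envelope,
$\phi = 1 - V_{material}/V_{domain}$, and the specific surface as
$S = SA/V_{domain}$ — the conventions under which the published design
table is internally consistent. For pure filament lattices the material
volume is computed exactly (to quadrature accuracy) by per-height
inclusion–exclusion of the two orthogonal strip families; arbitrary solids
fall back to centre-point voxel integration. Interface area is integrated
by quadrature over the primitive surfaces, discarding buried sample
points; filament end cuts flush with the lateral envelope are walls, not
fluid-facing surface. We note that the published specific-surface values
are not reproducible under any area/volume convention we could identify
(they move opposite to the pore-size trend that porosity follows), so `SA`
is reported but never used as a check.

## Flow model and solver

The perfusate is incompressible and Newtonian (defaults: blood at 37 °C,
$\rho$ = 1056 kg/m³, $\mu$ = 0.0045 Pa·s) in steady state with no body
force. At the study conditions the interstitial Reynolds number
$Re = \rho u d/\mu$ is at most ≈ 0.95 (0.45 mm pores at 9 mm/s), far below
both the Darcy-validity bound of 8.6 and any turbulence transition, so the
solver is laminar. (Reference simulations of these designs in commercial
finite-volume solvers sometimes enable a two-equation shear-stress-transport
turbulence closure; at $Re < 1$ such a closure should be inert, and the WSS
derivation itself assumes laminar flow, so no turbulence model is included
here.)
Isothermal conditions make the 37 °C setting enter only through the fluid
constants.

The steady Navier–Stokes equations are solved with a D3Q19
two-relaxation-time (TRT) lattice-Boltzmann scheme on the voxel domain:

- halfway bounce-back no-slip on every solid surface, with the TRT "magic"
  parameter fixed at 3/16 so the effective wall sits exactly halfway
  between fluid and solid voxel centres independently of viscosity;
- a uniform plug velocity on the inlet face, developed over a
  configurable entry length (default 1 mm of open channel);
- a zero-resistance outlet (zero gauge pressure, zeroth-order velocity
  extrapolation), via Guo non-equilibrium-extrapolation ghosts on both
  faces;
- lateral boundaries either no-slip walls (a one-voxel enclosure shell,
  or the elliptical envelope for graded designs) or periodic (unit-cell
  mode);
- deterministic initialisation: zero velocity, uniform density.

**Lattice scaling.** The voxel spacing fixes $\Delta x$; the time step is
chosen through the relaxation time $\tau^+$. Two caps pick
$\tau^+ \le 1$ automatically: the inlet velocity in lattice units stays
below 0.05 (Mach control), and the lattice density variation
$|\rho_{lat}-1|$ — proportional to the physical pressure drop divided by
$\rho\,c^2$ — stays below 0.005, which keeps the quasi-incompressible
approximation tight enough that the Darcy permeability extracted from the
solve is velocity-scale-free to a fraction of a percent. Because the
pressure drop is not known a priori, the solver measures it and, if the
headroom was exceeded, rescales $\tau^+$ and re-solves (at most twice,
deterministically); velocity sweeps avoid the extra pass by carrying the
pressure drop extrapolated from the previous velocity forward as
`expected_pressure_drop`.

**Convergence** is declared when the RMS momentum residual (the per-step
normalized velocity change, evaluated every 50 steps) falls below 1e-4
and the relative change of the velocity field between checks falls below
1e-6, simultaneously. Non-converged solves are returned flagged, with a
warning, never silently.

**Validation** rests on closed forms rather than reference-field
replication: plane Poiseuille (centreline $1.5\,\bar u$, wall shear
$6\mu\bar u/h$, permeability $h^2/12$), Hagen–Poiseuille (peak $2\,\bar
u$, permeability $R^2/8$), global mass balance, discrete divergence,
Stokes linearity, 0/90 rotational symmetry, and a square-duct
cross-check against an independently assembled sparse finite-difference
Laplacian solved with the Matrix package. The duct cross-check is held to
2%: the two discretizations are genuinely different schemes, so exact
agreement is neither expected nor meaningful.

## Wall shear stress

WSS is $\tau_w = \mu\,|\partial u_t/\partial n|$ evaluated on wall surface
elements — the voxel faces between scaffold solid and fluid inside the
scaffold extent (the enclosure shell is excluded). The voxelized surface
is a staircase, so each element carries a local outward normal estimated
from the occupancy moment of its 5×5×5 neighbourhood, and an effective
area equal to the voxel face projected onto that normal; by the divergence
theorem these projected areas sum to the smooth interface area. The normal
derivative is one-sided into the fluid: the default fits the tangential
velocity along the local normal through two trilinear samples, taken as
deep into the near-wall layer as the local pore allows (sample pairs from
(3, 5) down to (1, 2) voxel spacings, the first pair whose samples are
clean fluid), because samples hugging the staircase systematically
under-read the smooth-wall gradient. A strict first-order variant
(`order = 1`) is available; the two-point default was adopted after the
channel closed forms showed the single-sample scheme sitting at the edge
of its error budget. On the staircase a few percent of the smooth-wall
shear is irreducibly converted to form drag, which bounds the accuracy of
any gradient-based estimator; the channel fixtures hold the scheme to 5%.

The viability indicator is the area-weighted percentage of wall surface
with $\tau_w$ strictly below the threshold (default 30 mPa, configurable —
the osteogenic 0.11–10 mPa and mineralisation 0.55–24 mPa literature bands
can be requested as histogram edges). The published table calls the
analogous quantity a "percentage of volume"; a volume fraction of a
surface quantity is undefined, so this package computes and labels a
surface-area fraction, the only self-consistent reading.

## Desk-scale study sizes

Reference-grade simulations of these designs use body-fitted meshes of
several million tetrahedra. The
package runs the same physics at desk scale, and the test suite sizes
problems so the whole run stays within minutes on one CPU:

- rectangular designs default to **unit-cell mode**: one in-plane period
  ($d+d_f$ square) through the full ten-layer stack with periodic lateral
  boundaries, at 6 voxels per fibre diameter (0.055 mm). The unit cell
  reproduces the scaffold-interior porosity to within edge effects and is
  the domain for the Darcy-regime sweep properties.
- the graded design has no in-plane period, so ordering comparisons
  against the rectangular cases run the **full elliptical footprint at
  reduced scale** (0.4 × the in-plane dimensions, same fibre, pitch,
  stack and ring gradient) at a coarse matched spacing of ~0.1 mm
  (3–4 voxels per fibre, the resolution floor). This preserves the
  qualitative structure — a graded, more open network — while shrinking
  the domain to ~0.6 M voxels; the headline porosity comparison uses the
  full-size design, where construction and characterisation are cheap.
- voxel resolutions of 4/6/8 voxels per fibre bracket the defaults in the
  convergence checks.

What desk scale does **not** show: point-by-point agreement with the
published per-velocity viability percentages and contour fields. Those
come from body-fitted tetrahedral meshes of the full scaffold inside a
cylindrical enclosure, post-processed in a commercial solver with a
turbulence closure active; an interior unit cell, which excludes the slow outer
margins and enclosure bypass of the full assembly, sees systematically
higher WSS than a full-domain surface average. The package therefore
asserts the structure the study reports — porosity values and ordering,
monotone pressure-drop and viability trends, velocity-free permeability,
Darcy validity, and the graded design's advantage — plus the printed
table arithmetic, and treats the per-cell field values as out of scope.

## Numerical choices and degenerate inputs

- Voxel occupancy is a centre-point test; grids snap so an integer number
  of voxels covers the unit-cell period.
- Fluid voxels not 6-connected to the inlet are flagged as pockets and
  excluded from flow (idempotent filter); a domain with no inlet–outlet
  path is rejected as impermeable before solving.
- Pressure drop is read from plane-averaged virtual probes one voxel
  up/downstream of the scaffold, extrapolated half a voxel onto the
  scaffold faces with the local axial gradient.
- The Darcy length $L$ is the scaffold voxel extent times the spacing;
  permeability requires a strictly positive pressure drop.
- For graded designs the Reynolds length scale is the largest pore size
  (the conservative choice for the validity flag); the 8.6 bound is
  inclusive.
- Empty geometries report porosity 1 and zero surface; single-filament
  and single-ring specifications degenerate cleanly.
- WSS histogram bins are half-open with a closed final bin; the viability
  threshold itself uses a strict inequality, so a surface pinned exactly
  at the threshold counts as non-viable.

## Known limitations

- The published Case 1C porosity (61.19%) is inconsistent with its own
  pore size under the lay-down convention that reproduces the other two
  rectangular designs; the package reports what the stated parameters
  actually give (≈ 64.3%) rather than tuning the convention per case.
- Staircase walls limit per-element WSS accuracy to a few percent of the
  smooth-wall value; distributions near the viability threshold inherit
  that blur.
- The enclosure geometry of the reference study (a 1 mm radius cylinder
  around a 20 mm scaffold) cannot be dimensionally reconciled; domains
  here use the scaffold's own footprint as the duct cross-section with
  configurable entry/exit lengths.
- Rigid walls, Newtonian rheology, steady state: fluid–structure
  interaction, pulsatile flow and shear-thinning blood models are out of
  scope.
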