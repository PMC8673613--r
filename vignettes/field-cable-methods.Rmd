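---
title: "Volume-conductor and field-cable methods in dbsfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conductor and field-cable methods in dbsfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`dbsfield` compares finite-element volume-conductor (VC) methodologies for
current-controlled stimulation through a segmented directional deep brain
stimulation (DBS) lead. The comparison matrix crosses five implementations
of the current source on the active contact -- point current, boundary
current, current density, two-solve electric potential, floating potential
-- with explicit-domain or boundary-condition representations of the
active contact, the inactive contacts and the shaft, giving fifteen
admissible model variants (`variant_table()`). Each variant's
extracellular voltage distribution drives multi-compartment myelinated
axon models to activation thresholds, from which current-distance curves,
active-axon counts and activation volumes are compared across variants.

## Volume-conductor model

The quasi-static potential solves Laplace's equation
$\nabla\cdot(\sigma\nabla V_e)=0$ with isotropic conductivities: brain
0.2 S/m, encapsulation sheath (0.5 mm) 0.13 S/m, explicit
platinum/iridium contacts 5.3e6 S/m, explicit shaft insulation 1e-16 S/m.
Capacitive tissue properties and the electrode-electrolyte interface are
outside scope; the solution is the steady state of a current-controlled
pulse, scaled linearly in the commanded current (cathodic negative,
default -1 mA).

**Domain.** The lead is a parametric 8-contact directional design: a tip
band, two rows of three 90-degree segments (30-degree gaps), and a
cylindrical ring, all 1.5 mm long with 0.5 mm axial gaps on a 1.3
mm-diameter body. Lead dimensions are not standardized here; the defaults
follow the published directional-lead class and every dimension is a
`lead_spec()` parameter. The surrounding tissue is a bounded homogeneous
brain cylinder (radius 50 mm, about twice that in height) with a grounded
patch on the face opposite the tip and insulating boundary elsewhere. A
cylinder rather than a sphere keeps the structured grid exact around the
lead; at 75+ lead radii the far boundary's shape is immaterial to the
near-field comparison the package exercises. Anatomical head models and
heterogeneous/anisotropic tissue are non-goals.

**Mesh.** One structured tetrahedral parent mesh carries every lead
component as a labeled cell region: radial rings aligned to the material
radii (lead core, 0.1 mm contact shell, encapsulation, geometrically
graded brain), 15-degree azimuthal sectors aligned to the segment
boundaries, and axial layers aligned to the contact bands. Prisms are
split into tetrahedra by a global-index rule, so the mesh is conforming
and bit-deterministic. Every variant is a *cell-subset* of this parent
mesh: boundary-represented components are simply excluded from the finite
element domain, leaving their tissue interfaces as boundary surfaces.
This guarantees the active-contact surface discretization -- hashed by
`contact_surface_signature()` -- is identical across all fifteen
variants, which is essential for comparing integrated contact currents.
The default resolution (~96k tetrahedra) was accepted by a refinement
check (`convergence_check()`, `refine = 2` halves all element sizes)
showing ~2% voltage change on probe rings at 3-6 mm; the convergence
tolerance is configurable and defaults to 2%.

**Sources and boundary conditions.** All variants ground the distant
patch and treat the remaining outer boundary and shaft surfaces as
insulating (natural). Inactive contacts are ideal floating conductors:
in boundary representation all surface nodes are tied to one unknown
(DOF condensation -- the tied unknown is the floating potential and its
assembled equation is the zero-net-current constraint, which is exact);
in explicit representation the platinum conductivity itself enforces
equipotentiality. The five active-contact sources:

* *point current* -- Dirac load of the commanded current at the mesh
  vertex nearest the explicit contact domain's centroid (snap offset
  recorded);
* *boundary current* -- uniform flux-jump load `I/A` on the interior
  contact-tissue interface of the explicit contact;
* *current density* -- Neumann condition `sigma dV/dn = I/A` on the
  exterior surface of the boundary-represented contact;
* *electric potential* -- two solves: a Dirichlet seed (default 1 V) on
  the contact surface whose delivered current `I1` is measured, then a
  second solve with the seed rescaled by `I/I1` (by linearity the second
  solve equals the first times the ratio; both are performed and the
  equality is asserted in tests);
* *floating potential* -- the contact surface tied to one unknown with
  the commanded current loaded on it (equipotential with exact total
  current).

**Linear algebra.** P1 stiffness is assembled vectorized; systems are
solved by conjugate gradients preconditioned with incomplete Cholesky
IC(0) after symmetric Jacobi scaling (relative residual 1e-12, far below
the 1e-10 target). The direct sparse path is retained as an option.

**Contact currents.** The delivered current is integrated as the
consistent (reaction) flux: the assembled tissue-side residual summed
over the contact's surface nodes, which is the discrete
$\oint \sigma \partial V/\partial n\, dA$ seen from the tissue -- the
flux-*difference* form for an interior boundary, never the two-sided
average, which is known to misreport boundary-current sources. A direct
facet-gradient quadrature is kept as a diagnostic only; its one-sided
O(h) error at the edge singularities is large by construction. For the
point source the contact-tissue interface is the only conducting exit of
the contact domain (all other faces border the 1e-16 S/m insulation), so
the open interface integral equals the closed-surface integral up to
that leak.

**Current-density maps.** `surface_current_density_map()` reports, per
facet: the tissue-side normal component (for the pure Neumann source the
imposed value, which is the solution's normal trace), the tissue-side
magnitude including the tangential component computed from the facet's
own nodal potentials, and -- for explicit contacts -- the contact-side
magnitude. Distributed sources concentrate current at contact edges and
corners (`edge_center_ratio() > 1`). The point source additionally shows
a center peak *inside the conductor*: the weld-point convergence current
scales as $I/(4\pi r^2)$ near the load, which is why the map carries the
contact-side column; an ideal conductor's tissue-side density is
edge-singular with no center structure.

## Axon model

Each axon is a straight MRG-class myelinated fiber (default 5.7 um, 21
nodes of Ranvier, internode length 500 um from the published
diameter-geometry table). Nodes carry fast Na+, persistent Na+, slow K+
and leak conductances with the published kinetics (reference 36 C,
Q10-scaled to the 37 C default). Internodes use the reduced single-cable
representation: three passive compartments per internode whose specific
conductance and capacitance lump the axolemma in series with the 160
myelin membranes; the explicit double-cable paranode structure is not
implemented. The nodal leak reversal is balanced so the fiber rests
exactly at -80 mV, the standard initialization for this model family;
resting drift is below 1e-11 mV over the simulated window.

Extracellular drive: the VC solution (per commanded 1 mA cathodic) is
interpolated at compartment centers (`attach_field()`) and scaled by the
stimulus waveform -- monophasic rectangular, 60 us, onset delay 100 us,
3 ms window -- and the amplitude. The cable equation is integrated by a
semi-implicit Crank-Nicolson scheme (dt = 2 us; gates by Rush-Larsen
with tabulated rate functions; tridiagonal Thomas solve in C++). A fiber
is *activated* when the membrane crosses 0 mV at the 2nd node from both
ends after pulse onset -- an AP at one end only (blocked propagation)
does not count. Halving dt changes thresholds by well under 1%.

## Population thresholds and activation metrics

The axon grid is perpendicular to the lead and centered on the active
contact: 10 log-spaced radii from 1.5 to 8 mm (the lower bound clears the
1.15 mm lead-plus-encapsulation radius; the nominal 1 mm choice would sit
inside the sheath), axial offsets -3..+3 mm, and the grid rotated around
the lead in 30-degree steps. The rotated subset retains the axial offsets
so that the revolve volume estimator has axial support. Axons run
tangentially, so the grid radius is each fiber's closest approach to the
axis.

Thresholds are found by bisection over 0.05-10 mA to 1% relative bracket
width; axons outside the range are reported unconverged with the reason.
A 0.5%-step amplitude-sweep oracle agrees with bisection within one step.
Activation at an amplitude is summarized as the active-axon count and an
activation volume that revolves the per-azimuth, per-offset largest
activated radius (`0.5 * dtheta * r_max^2 * dz` summed over sectors) --
taken directly from the rotated-grid design, avoiding convex-hull
artifacts.

## The variant comparison and what it shows

`run_matrix()` executes geometry, solve, interpolation and thresholds for
each variant on the *same* parent mesh and axon grid, reporting per-axon
threshold errors, voltage-difference maps (probes within two element
diameters of a point-source vertex excluded), population errors and
per-stage timings (informational only; never an acceptance quantity).

A finding this implementation makes explicit: with a shared mesh, exact
floating/Dirichlet current control and consistent flux measurement, the
four ideal-conductor source implementations produce the *same* exterior
field to solver precision, and explicit-versus-boundary representations
of the insulating shaft (1e-16 S/m versus excluded cells) and of the
inactive contacts (platinum domain versus tied surface) coincide
numerically. Individual threshold errors for those variants are therefore
exactly zero after bisection quantization. The genuinely different
physics is the current-density source -- the only non-equipotential
contact model -- which at the default reduced scale produces individual
threshold errors of roughly -11% to +9% that aggregate to only about
-1% (counts) and -3% (volume): the population-level damping of
implementation differences, the comparison's headline property, holds.
Workflows that remesh the geometry for every variant, or that integrate
contact currents by averaging the two-sided surface flux, add further
spread on top of this; the matched-mesh, consistent-flux design
deliberately removes those artifacts, so the package quantifies the
methodological floor of the source/geometry representation itself.

## Verification oracles

* *Analytic*: a point source at the center of a fully grounded sphere
  (`sphere_mesh()`, radius 4000 mm, octahedral geodesic shells graded
  1.12x near field) has the closed form
  $V = I/(4\pi\sigma)(1/r - 1/R)$; the FEM solution matches within 2%
  over 2-25 mm against both the bounded form and the infinite-medium
  $I/(4\pi\sigma r)$ (boundary bias at 25 mm is r/R = 0.6%). The oracle
  sphere is deliberately far larger than the 50 mm brain domain: in any
  bounded domain of radius R the infinite-medium formula is only valid
  where r << R, so the control geometry is sized so the probe range
  satisfies that.
* *Equivalence*: the floating-potential and two-solve electric-potential
  sources impose the same mathematical problem (equipotential surface at
  total current I); their fields agree to ~1e-12 RMS, asserted at 1%.
* *Conservation*: every source delivers the commanded current within
  1e-9 relative (consistent flux is discretely exact); inactive floating
  contacts carry < 1e-13 mA.
* *Cable*: monotone all-or-none recruitment, strength-duration
  monotonicity (30/60/120 us), exact halving of threshold under doubling
  of the static potentials, sweep-versus-bisection agreement, dt
  convergence.

## Numerical choices and degenerate inputs

Ties are resolved deterministically (lowest index) when snapping the
point-source vertex; a zero-area active surface, a seed solve delivering
no current, a disconnected floating surface (singular system), meshes
without a ground patch, axons placed inside the lead, and non-monotone
bisection brackets are all hard errors with named causes. The entire
pipeline is deterministic: meshing uses no randomness, bisection is a
fixed sequence, and the comparison matrix hashes identically run-to-run.

## Problem sizes

Defaults were chosen as the package's study scale: ~96k tetrahedra
(~17k vertices) for the lead mesh, ~250k for the oracle sphere, 600
axons x 81 compartments for the full rotated grid, 15 variants. The test
suite exercises coarser meshes (~54k tets) and a 144-axon rotated grid
for the full matrix; all sizes are arguments.

## Limitations

The synthetic domain emulates near-electrode field structure in
homogeneous tissue; it does not emulate anatomical boundaries,
heterogeneous or anisotropic conductivity, electrode-tissue interface
impedance, charge-balanced waveforms, curved or branched axons, or fiber
populations with mixed diameters. Passing tests therefore validate the
comparison of VC methodologies under these idealized conditions, not
patient-specific activation predictions. Absolute thresholds of the
reduced-internode fiber are systematically lower than the full
double-cable model would give; the cross-variant comparisons, which are
the package's purpose, are relative quantities.
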