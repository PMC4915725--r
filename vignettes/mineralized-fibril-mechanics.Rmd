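---
title: "Mesoscale mechanics of mineralized collagen fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale mechanics of mineralized collagen fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minfibril)
```

## The model

`minfibril` simulates one mineralized collagen fibril at the mesoscale. A
tropocollagen molecule is a chain of beads spaced 14 Å along its contour;
hydroxyapatite is a second bead species. The potential energy separates into
collagen, mineral and interface terms,

$$E_{total} = E_{collagen} + E_{HAP} + E_{inter}, \qquad
  E_{collagen} = E_{bond} + E_{angle} + E_{non\text{-}bonded},$$

with three interaction families:

* **Bonds** (backbone and crosslinks) are bilinear breakable springs: force
  $k_T^{(0)}(r - r_0)$ up to the hyperelastic distance $r_1$, a stiffer
  branch $k_T^{(1)}(r - r_0)$ up to $r_{break}$, and zero permanently
  beyond. With $r_0 = 14.00$, $r_1 = 18.20$, $r_{break} = 21.00$ Å,
  $k_T^{(0)} = 17.13$ and $k_T^{(1)} = 97.66$ kcal mol⁻¹ Å⁻², a chain
  stretches elastically, stiffens by the factor $k_T^{(1)}/k_T^{(0)} =
  5.70$, and ruptures at $(21-14)/14 = 50\%$ bond strain. Rupture is
  irreversible within a run.
* **Angles** are harmonic in the bead-triple angle,
  $\tfrac12 k_B(\varphi - \varphi_i)^2$ with $k_B = 14.98$
  kcal mol⁻¹ rad⁻², against one of 13 integer equilibrium angles between
  164° and 180° assigned from the initial (crimped) geometry.
* **Pairs** are truncated 12-6 Lennard-Jones potentials in three classes:
  collagen–collagen ($\sigma$ 14.72 Å, $\epsilon$ 6.87 kcal/mol),
  mineral–mineral (10.28 Å, 106.7 kcal/mol, cutoff 13.85 Å) and
  collagen–mineral (9.88 Å, 137.1 kcal/mol, cutoff 20 Å). Bonded (1–2) and
  angle-spanning (1–3) pairs are excluded, standard practice for calibrated
  bonded models. Energies are plainly truncated by default; a cutoff-shift
  toggle exists because thermostated dynamics tolerate either convention.

Units are Å, fs, amu, kcal/mol. Two conversion constants fix every reported
mechanical number: 1 kcal mol⁻¹ Å⁻¹ = 69.479 pN, hence 1 kcal mol⁻¹ Å⁻³ =
6.9479 GPa. Bead masses are 1324 amu (collagen) and 1548 amu (mineral); the
published parameter table lists two mesoscale particle masses and we read
the 1324-amu row as the collagen bead — the mass of a 14-Å triple-helix
segment — with both values configurable should that reading be revised.

## Geometry construction

The default fibril is a 20-nm-diameter cylinder of quarter-staggered
molecules with a 670-Å D-period and five gap/overlap periods per periodic
box (axis $x$). Two printed counts pin the construction: 158 molecules and
28,305 collagen beads. Because neither the cross-section lattice constants
nor the per-molecule bead count are published, both are calibrated:

* Molecules sit on a quasi-hexagonal lattice whose constant is chosen so
  that a cylinder of the requested diameter contains exactly the target
  number of chains. An irrational lattice-centre offset makes site radii
  pairwise distinct, so the count changes one site at a time and the
  calibration is exact and deterministic (the default yields a constant of
  ≈ 15.0 Å).
* The bead total divides as evenly as possible over molecules: 179 beads
  per molecule with the 23 remaining beads assigned one each to the first
  molecules in a fixed ordering (phase, then radius, then azimuth). The
  implied ≈ 250-nm stored contour is shorter than the nominal 300-nm
  molecule; we treat the printed bead totals as authoritative and absorb
  the difference into this calibration.
* Stagger phases follow the standard five-class quarter-stagger assignment
  $(i + 2j) \bmod 5$ on lattice indices; phase $c$ molecules start at
  $cD$. With the gap:overlap split fixed at 0.54:0.46 of $D$ (standard
  collagen values, not printed), molecule spans equal $3.46\,D$, which
  makes every cross-section contain 4 stagger classes in overlap zones and
  3 in gaps.

**Crimp.** Molecules are wavy at rest. We impose a global transverse
displacement field $y \mathrel{+}= A\sin(2\pi n_w x/L_x)$ and place beads at
equal arc length along it, which (i) contracts the axial span to match the
0.54:0.46 registry exactly — the slope amplitude $u$ is solved numerically
from the span/contour ratio — and (ii) generates the discrete set of
equilibrium angles. The wavenumber is snapped to an integer count per box
(periodicity across the seam) and capped so consecutive bonds never bend
more than 12.5°, which after rounding gives at most 13 integer angles in
[168, 180]. Because the field is global, all chains deform coherently and
never interpenetrate. The toe region of the stress–strain curve (initial
uncrimping) is the direct mechanical signature of this waviness.

**Mineralization.** Mineral beads occupy a face-centred close-packed
lattice at the pair-equilibrium spacing $2^{1/6}\sigma_{HAP} = 11.5$ Å,
grown outward from the two molecular terminal planes that bound each gap
region, clipped to the fibril cylinder, excluding sites within 9.5 Å of a
collagen bead. Sites are consumed in order of distance to the nearest
terminal plane, so low densities produce two distinct crystals per gap and
high densities fill the gap. Each crystal is shifted rigidly onto the crimp
field (field value at its terminal plane), preserving its internal lattice.
The bead count follows the weight-fraction identity
$w = N_{min}m_{min}/(N_{min}m_{min} + N_{coll}m_{coll})$ and the builder
enforces ±0.5 percentage points; the published per-density mineral bead
counts (2,037–28,962) are not consistent with this identity under either
mass assignment, so they are treated as calibration references only.

**Crosslinks.** "Two trivalent crosslinks per molecule" is realized as one
crosslink bond per molecule end, attaching the end bead to the nearest bead
of another molecule within 22 Å. Crosslink bonds reuse the backbone
bilinear parameters with a configurable scale on $r_{break}$ (default 1.0)
— their parameters are a free input of the model, not published.

## Dynamics

The integrator is velocity Verlet, $\Delta t = 10$ fs, with a Langevin
thermostat at 300 K (damping 1000 fs — weak enough not to mask slip
dynamics; a vacuum system needs a local thermostat). No solvent or
viscosity is modelled. Equilibration couples the axial box length to a
Berendsen-style relaxation toward zero axial virial stress (time constant
5000 fs, stress scale 5 GPa, per-step change clamped at $2\times10^{-4}$);
lateral boundaries are open vacuum wider than the largest cutoff.
Convergence is judged by a levelling positional RMSD. Tensile tests deform
the box at a constant displacement rate with an affine remap of coordinates
and velocities each step (barostat off), to a target strain; 1 m/s equals
$10^{-4}$ Å per step. The Verlet neighbour list (2-Å skin) rebuilds
whenever any bead moves half a skin since the last build; affine box
changes rescale the stored reference positions so the same displacement
criterion covers them. All stochastic streams derive from one integer seed,
and force reduction order is fixed, so trajectories are bit-reproducible.

Stress is the tension-positive axial virial over the fibril volume
$\pi(d/2)^2 L_{box}$ with the diameter held constant at its build value
(20 nm default); the kinetic term is included and toggleable. Mineral
"internal stress" is the same sum restricted to mineral beads, normalized
by the *total* fibril volume — a declared convention, since none is
published. For single molecules the volume convention is the
hexagonal-packing cell at the collagen pair-equilibrium spacing,
$A = (\sqrt3/2)(2^{1/6}\sigma_{coll})^2 = 236.3$ Å², chosen a priori as
the cross-section a molecule occupies in the fibril lattice; under it the
closed-form small-strain modulus is $k_T^{(0)} r_0/A = 7.05$ GPa,
matching the known single-molecule value of ≈ 7 GPa. Because box
deformation can only load a structure that percolates the periodic axis,
single-molecule tension uses an axially periodic chain (the box length
equals the closed-chain contour); its response is that of the molecule
interior, and rupture at one bond unloads the whole chain.

## Analysis

`segment_regimes()` smooths the curve (centred moving average over a
1%-strain window; the raw curve is kept for toughness), decimates it, and
fits a piecewise-linear model by exact dynamic-programming change-point
detection with BIC model selection (minimum five points per segment).
Segments are labelled sequentially: toe (initial slope under half of the
next segment, ending by 12% strain), elastic I-a, an optional distinct
intermediate I-b, a sliding regime II (slope drop, saw-tooth oscillation),
stiffening III, and post-peak IV. The published regime boundaries are read
off curves visually; this change-point procedure is our declared
substitute.

Toughness is the trapezoidal integral of the raw curve up to the ultimate
point. The ultimate point is the global stress maximum with ties resolved
to the *last* attaining sample, so flat-topped curves integrate over their
plateau; an opt-in guard flags curves truncated while still rising.
Contraction is quoted against the unmineralized reference length $L_0$,
and internal stress is measured by re-extending the relaxed box affinely
to $L_0$ and holding it under the thermostat. Strain is interconvertible
between the relaxed-length and fixed-$L_0$ conventions through the stored
lengths, $\epsilon_{L_0} = (L_{relaxed}/L_0)(1+\epsilon) - 1$.
Density-normalized performance divides toughness and ultimate stress by
the fibril mass relative to the collagen-only fibril (volumes cancel under
the constant-diameter convention).

## What the test systems emulate — and what they do not

Full-scale reproduction of the reference fibril curves (158 molecules,
tens of millions of pulling steps) is cluster-scale. The package's own
evidence comes from three tiers, fixed once as study conditions:

1. **Exact oracles** — forces against numerical gradients, neighbour-listed
   sums against brute-force $O(N^2)$ loops, builder counts, conversion
   constants. These are scale-free.
2. **Single molecule** (215 beads, periodic chain, 300 K, 8–16 m/s):
   closed-form bilinear mechanics — slope ratio 5.70, rupture near 50%
   strain, small-strain modulus ≈ 7 GPa.
3. **Mini-fibril testbed**: diameter 5 nm, D-period 335 Å, two periods
   (670-Å box), near-straight molecules, 2-ns equilibration, pulls at
   160 m/s to 280% strain (relaxed-length convention; mineral-contracted
   states re-extend far before loading). The testbed's molecules are built
   near-straight rather than crimped: a coherent global crimp is a soft
   deformation mode — every chain can deepen the same wave at zero
   Lennard-Jones cost — and at this miniature scale it lets the fibril
   compact without the excluded-volume resistance a full-size,
   incoherently crimped fibril has. With straight chains, axial compaction
   must buckle molecules individually, and the density dependence of
   mineral-driven contraction (weak drive at low density, gap closure at
   mid density, pre-filled jammed gaps at high density) re-emerges. The
   testbed preserves the architecture (quarter stagger, gap
   mineralization, adhesion-dominated slippage) but not the numbers: with
   an order of magnitude fewer molecules the structure is far more
   compliant, contraction is exaggerated (tens of per cent rather than
   the full-scale ≤ 20%), and the pull rate is far above the 1 m/s
   reference. Trend and ordering checks — ultimate stress rising
   with density, contraction peaking in the mid-density band, broken-bond
   monotonicity, saw-tooth sliding at mid densities, regime III steeper
   than I-a, crosslink-induced brittleness — are meaningful at this
   scale. One caveat: the miniature mineral-only fibril fails by pure
   slippage (no molecular rupture inside the pull window), so the
   crosslink comparison is made on the rupture onset — crosslinked
   fibrils break molecules strictly earlier — rather than on ultimate
   strain, whose full-scale comparison presumes both systems reach
   rupture-driven failure; absolute moduli, strengths and contraction percentages are not,
   and passing them says nothing quantitative about real (or full-scale
   simulated) fibrils.

Problem sizes used by the shipped tests and the acceptance script: the
default builder (28k beads, geometry only), one 215-bead molecule pulled
for ~1e6 steps, and ~350–550-bead mini-fibrils equilibrated for 2e5 steps
and pulled for up to ~1e6 steps.

## Numerical choices and degenerate inputs

* Bond branches follow the printed piecewise force exactly; the force is
  discontinuous at $r_1$ (printed as such) while the energy is its
  continuous antiderivative. A bond exactly at $r_{break}$ counts as
  broken (≥ comparison). Broken bonds keep their 1–2 pair exclusion.
* Collinear angle triples have an undefined angle gradient; they
  contribute energy but zero force and are counted per evaluation.
* Pair distances below 0.8 Å abort the evaluation naming the offending
  beads (overlap guard).
* The collagen–collagen cutoff is unpublished; the default $2.5\sigma$ =
  36.8 Å spans the adhesive well that sets intermolecular cohesion.
* Ties in the lattice calibration are impossible by construction
  (irrational centre offset); ties at the ultimate point go to the last
  sample.
* The toughness error for curves "truncated before their maximum" is
  opt-in (`require_interior_max`), because rectangle- and triangle-shaped
  curves with their maximum at the final sample are legitimate inputs.

## Known limitations

Dry fibrils only (no water, no viscosity), ideal hydroxyapatite beads (no
substitutions), no electrostatics, no bond reformation, no extrafibrillar
mineral, no GPU path, and a Berendsen-style axial relaxation rather than a
rigorous Nosé–Hoover NPT. The mini-fibril testbed exaggerates contraction
and rate effects as discussed above. Crosslink bond parameters are a
declared free parameter.
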