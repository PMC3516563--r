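---
title: "Mapping electron-transfer epitopes by exhaustive rigid-body sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping electron-transfer epitopes by exhaustive rigid-body sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmap)
```

## The question the method answers

Transient redox complexes — cytochrome *c* against its reductase, oxidase,
peroxidase, sulfite oxidase, flavocytochrome *b*~2~ and similar partners —
exchange electrons through short-lived, weakly specific encounters.  A
crystal structure, when one exists, shows a single binding geometry; the
physiologically relevant quantity is rather the *set* of geometries from
which tunneling is fast.  `redoxmap` delineates that set from steric
information alone: it slides a mobile redox protein over the whole surface
of its partner, asks at every placement how close the two redox cofactors
can get without steric conflict, and converts those distances into
upper-limit electron-transfer (ET) rates.  The output is a functional
epitope: the surface region of the partner over which the mobile protein's
best docking geometry supports an ET rate above a threshold (10^6^ s^-1^
by default).

Both proteins are treated as rigid bodies.  The flexibility that real side
chains would contribute at the interface is absorbed by a *reduced*
repulsion scheme (below) instead of explicit repacking.

## Translational sampling

The fixed protein's centre of mass (CM) sits at the origin; the mobile
protein's CM starts on the positive *z* axis at the CM separation *d* of
the input structures.  A spherical grid of CM directions is built so that
neighbouring CM positions are about δd apart (1 Å by default):
δθ = δd / d rotational increments about the *x* axis, n~θ~ = trunc(π/δθ)
rings, and per ring δφ~i~ = δd / (d sin θ~i~) increments about the *z*
axis with n~φ,i~ = max(1, trunc(2π/δφ~i~)) steps.  Truncation (rather than
rounding up) keeps the realised spacing at or above the requested
resolution; polar rings collapse to a single point, and every ring starts
at φ = 0.  The radial coordinate is not part of the grid: at every (θ, φ)
the mobile protein is translated along the CM–CM line until it makes
steric contact, and the CM separation *r* at contact becomes the radial
coordinate of that solution.

For flat, elongated receptor regions (membrane-protein faces), a
cylindrical variant replaces the sphere: translation levels spaced δd
apart along the long axis of the fixed structure (the largest-spread
principal axis of its mass-weighted gyration tensor, user-overridable)
and, per level, angular steps of δd divided by the cylinder radius.

## Rotational sampling

At each CM placement the mobile body is rotated about three orthogonal
axes through its CM: χ about the normal of the plane through the two CMs
and the mobile cofactor's reference point (the heme Fe in the motivating
systems), ξ about the CM–CM line, and ψ about their common perpendicular.
Rotations compose extrinsically in the order χ, ψ, ξ.  Two enumeration
protocols are provided:

* **full**: χ, ψ ∈ [0°, 360°), ξ ∈ [0°, 180°), equal increments δ —
  186,624 rotamers per CM at δ = 5°;
* **reduced composite**: χ, ψ ∈ [−45°, 45°) at 5° with ξ ∈ [0°, 360°) at
  15° — 7,776 rotamers per CM, a 24-fold saving.

All intervals are half-open.  A closed-interval reading of the reduced
ranges (−45° through +45° inclusive) would give 19 values per axis at 5°
and an enumeration of 8,664; the half-open convention gives exactly
7,776 = 18 · 18 · 24, the count the 24-fold saving refers to, and is
adopted throughout.

The reduced protocol only reaches short cofactor–cofactor distances if the
mobile cofactor already faces the partner.  `frontal_align()` therefore
scans the full 5° rotational space once, at the starting CM position, for
the body rotation minimising the cofactor–cofactor distance; that
orientation is then carried along with every grid placement (the placement
rotation acts on position and orientation together), so the cofactor keeps
facing the fixed protein over the whole sphere.  The χ/ψ/ξ axes are built
from the cofactor's *pre-alignment* reference point: after alignment the
cofactor lies on the CM–CM line by construction, where the plane of the
axis definition degenerates.  If the reference point is collinear with the
CMs already, an arbitrary perpendicular completes the frame — with χ and ψ
ranges symmetric about zero, the azimuthal phase of the χ/ψ pair is
immaterial.

## Steric contact

Steric acceptability is judged by a purely repulsive quartic potential
summed over intermolecular heavy-atom pairs within a non-bonded cutoff
(8.5 Å default, the permissive end of the customary 5.5–8.5 Å range):

f~vdW~ = k~vdW~ Σ~ij~ max(0, (s·r~min,ij~)² − r~ij~²)²,

with scale s = 0.75, force constant k~vdW~ = 20 kcal mol^-1^ Å^-4^, and
r~min,ij~ the sum of the two atoms' contact radii (a Bondi-style
per-element table ships with the package and is user-replaceable; an
arithmetic-mean combination rule is available as a switch).  Under the
**reduced** scheme the sum skips all side-chain atoms beyond C~β~,
mimicking the uncertainty of side-chain positions upon binding;
backbone atoms, C~β~ and all non-amino-acid (cofactor/hetero) atoms stay
active.  Whether cofactor atoms belonged to the active set in the original
protocol is not documented; they are kept active here because a cofactor
that a probe can pass through would corrupt the distance of closest
approach — the quantity the whole method rests on.

`translate_to_contact()` moves the mobile body along the CM–CM line to the
largest separation at which 0 < f~vdW~ ≤ E~cut~ (10 kcal/mol by default,
a value rigid-body docking practice finds to yield realistic complex
mimics; 300 kcal/mol
for permissive runs).  The boundary is located by stepping inward 0.1 Å to
the first positive-energy position and bisecting the zero/positive
boundary to 0.01 Å.  Because the energy is an explicit piecewise
polynomial along the line, the implementation brackets the boundary
analytically per atom pair before stepping; the returned pose is still the
stepping/bisection result, it is just found without scanning from afar.  A
body that starts overlapped is receded first, so the result is independent
of the starting separation.  Lines on which no positive energy exists
(grazing geometries) are reported as contact-free and counted, not raised
as errors.

For each rotamer the minimal cofactor edge-to-edge distance — the minimum
over heavy-atom pairs, one atom from each cofactor group — is evaluated at
the contact pose only, and the rotamer with the smallest distance is kept
per CM (ties resolve to the lexicographically smallest (χ, ψ, ξ)).  The
engine contains no randomness: identical inputs give bit-identical maps.

## From distances to rates

Distances convert to non-adiabatic ET rates with the tunneling distance
ruler combined with the classical Marcus activation term:

k~ET~ = k~0~ · exp(−β (r − r~0~)) · exp(−(ΔG° + λ)² / (4 λ k~B~ T)),

with k~0~ = 10^13^ s^-1^ (nuclear frequency), β = 1.4 Å^-1^ (through-protein
coupling decay), r~0~ = 3.6 Å (van der Waals contact).  ΔG° and λ are
system-specific inputs in eV; the temperature defaults to 298.15 K
(standard conditions; the endergonic-tunneling benchmark values the test
suite checks are reproduced at this temperature within their distance
rounding).
Distances below r~0~ — possible because the quartic onset with s = 0.75
permits closer approach than van der Waals contact — are clamped to r~0~
with a warning rather than extrapolated above k~0~, since the ruler is
parameterised from contact outwards.  These are *upper-limit* rates: no
population weighting over orientations is attempted.

Epitope summaries comprise the upper-limit k~ET~ (map-wide maximum), the
epitope size (number of CMs with k~ET~ above the threshold), and the
top-decile mean — the average over the 10% most ET-active orientations,
defined here as: restrict to above-threshold solutions, average the top
ceil(0.1·n) by rate.  The alternative reading (10% of *all* orientations)
changes the statistic only when fewer than 10% of orientations pass the
threshold and is not used.

## Ternary complexes and conformer ensembles

A second probe molecule is handled by sampling it against the receptor
exactly as in the binary mode — deliberately ignoring the already-bound
first probe — and then discarding every solution whose probe–probe quartic
energy exceeds the cutoff.  This reproduces the two-step protocol used for
the oxidase low-affinity site and for multidomain enzymes.

Receptor flexibility enters through conformer ensembles.  Multi-model PDB
ensembles are read directly.  For tethered two-domain systems the package
also generates ensembles itself: the two domains are kept internally
rigid while torsions about the linker backbone bonds are drawn uniformly,
and a draw is accepted only if the domain–domain and domain–linker quartic
energies pass the cutoff.  This is a deliberately simple, seed-deterministic
stand-in for torsion-angle simulated annealing with knowledge-based
potentials: the downstream epitope analysis is independent of how
conformers are produced, and outputs flag the sampler as simplified.
Ensemble statistics use the sample (n−1) standard deviation, and 100
conformers is the default ensemble size.

## The synthetic test substrate

Real inputs for this class of analysis are curated PDB complexes with
modelled loops and many CPU-hours of sampling; neither belongs in a test
suite.  The package instead ships a generator of toy "proteins" with
analytic ground truth: quasi-uniform spherical atom shells (deterministic
Fibonacci-spiral placement, so fixtures are identical across platforms)
with one single-atom cofactor protruding slightly at a chosen surface
direction.  Because all atoms share one contact radius, the minimal
achievable cofactor–cofactor distance when the two bodies meet
cofactor-to-cofactor is known in closed form from the quartic onset:
s · 2 r~atom~ (2.55 Å at the defaults).  The generator also returns a
documented discretization bound combining the grid resolution, the
rotational increments and the contact-search tolerance, against which the
engine's global minimum is tested, together with a dense random-rotation
oracle that the engine must never beat by more than that bound.  A
two-shell variant joined by a zig-zag pseudo-linker exercises the ensemble
machinery: its second-domain cofactor faces the first domain and is
occluded in the extended conformation, and torsion ensembles expose it —
the multidomain-mobility phenomenon in miniature.

What the toys do *not* emulate: real atom-density heterogeneity, concave
binding sites, multi-atom cofactors with anisotropic edges, and real
side-chain topology (every shell atom is backbone-like and vdW-active).
Passing tests therefore validate the sampling, contact and rate machinery,
not biological conclusions about any particular complex.

## Problem sizes and numerical choices

The test suite and the acceptance script run the protocol-equivalence
comparison (full 5° scheme, 186,624 rotamers per CM, against the reduced
composite scheme) on a 12-atom-per-shell toy pair over a 32-point coarse
grid, and the end-to-end demonstration on a 32-atom-per-shell pair at
δd = 2 Å with 15°/45° composite rotamers (about 1,200 CMs); both complete
in well under a minute on one core.  Published-scale runs (δd = 1 Å,
7,776 rotamers per CM, receptors of thousands of atoms) use the same code
paths and scale linearly in grid points × rotamers × atom pairs.

Numerical conventions collected in one place: half-open rotation
intervals; truncation toward zero in the grid-count formulas; pole rings
collapse to one point; per-CM ties broken lexicographically; contact
bisection to 0.01 Å; contact-free CMs recorded as absent (not infinite);
cofactor distances evaluated at the contact pose only; mass-weighted
centres of mass (geometric centroid available as a switch); highest
occupancy wins alternate locations with ties to altloc "A"; hydrogens are
ignored everywhere (radius tables and edge-to-edge distances are
heavy-atom conventions).

## Limitations

The method scores sterics only: no electrostatics, desolvation or
attractive dispersion, so epitope sizes measure geometric accessibility,
not binding probability.  Rates are upper limits through a single
isotropic decay constant β; pathway-specific couplings are out of scope,
as are side-chain repacking and electrostatic surface analyses.  The
linker-conformer sampler
makes no claim of Boltzmann realism — it bounds what geometry and sterics
allow, which is exactly what the ensemble epitope statistics need.
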