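---
title: "Hydrophobic portraits of ion-channel pores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrophobic portraits of ion-channel pores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremapr)
```

## The problem

Cryo-EM routinely delivers several conformations of the same tetrameric ion
channel — open, closed, and states in between. The minimal gate radius alone
does not decide whether a pore conducts: a narrow *hydrophobic* stretch can
dewet and block ions without steric occlusion, while a geometrically
"open-looking" pore can stay dry. `poremapr` characterises pore states by
combining four quantitative descriptors of the permeation pathway:

1. **Pore geometry** — a HOLE-style radius profile along the pore axis and
   the minimal gate radius $R_{gate}$.
2. **Surface hydrophobicity** — the molecular hydrophobicity potential
   (MHP) mapped onto cylindrical projections of the van der Waals surface,
   decomposed into self and induced subunit contributions.
3. **Residue packing** — per-residue 3D–1D environment scores and their
   correlation across states and channel subtypes.
4. **Hydration** — water-exposed (Connolly) surface area and water/ion
   density profiles over trajectory frames, plus permeation counting.

Together with detection of π-bulges in the pore-lining helices, these feed
a deterministic rule table that labels a structure α-closed, π-closed,
π-open or intermediate.

## Models and procedures

### Molecular hydrophobicity potential

Every protein heavy atom carries an empirical hydrophobicity constant
$f_i$ on the octanol–water logP scale. The MHP at a point $j$ is the
attenuated superposition

$$\mathrm{MHP}_j = \sum_{i,\; r_{ij} < r_{cut}} f_i\, e^{-r_{ij}/2},$$

with distances in Å, a decay length of 2 Å and a hard cutoff
$r_{cut} = 9$ Å (the contribution is identically zero at and beyond the
cutoff; no shifting or smoothing — the truncation error at 9 Å is
$e^{-4.5} \approx 0.01$ per unit constant and cancels in sign
comparisons). For a surface point owned by one subunit, the sum over that
subunit's atoms is the *self* MHP, the sum over all other subunits the
*induced* MHP; the package computes the two partitions separately so that
self + induced = total holds exactly, not merely to rounding.

The constants are united-atom Wildman–Crippen atomic logP contributions:
each amino acid was typed in a Gly-X-Gly mid-chain context with explicit
hydrogens, and each hydrogen's contribution folded onto its bonded heavy
atom (`hydrophobicity_table()`, versioned CSV). Cryo-EM depositions
usually lack hydrogens, so operating on heavy atoms with implicit-H
adjusted constants avoids a protonation step the input cannot support;
when a file does contain hydrogens they are typed with constant zero
because their share is already counted. Waters, ions and lipids never
enter MHP sums — the maps characterise the protein surface.

### Cylindrical projection by ray tracing

The 2D maps follow a five-step procedure: (1) the pore axis is a cubic
spline through the centres of mass of C$_\alpha$ quadruplets of
symmetry-related residues (for TRPV1: 642–645, 671, 675, 676, 679, 680,
683, 686; shipped per channel in `channel_config()`); (2) a regular
(z, angle) grid is laid on an enclosing cylinder whose radius is computed
to contain every atom in every section, with one ray per node starting on
the local axis point and running orthogonal to the local tangent; (3) each
ray is traced to its *nearest* intersection with any van der Waals sphere;
(4) the property (MHP or a residue score) is evaluated at the hit point;
(5) values are collected on the grid. Angular integration (the mean over
non-miss nodes per z row) yields 1D self/induced/total profiles.

Ray–sphere search is accelerated with a 3DDDA voxel traversal: atoms are
binned into a uniform grid (default 3 Å voxels), each ray walks only the
voxels it crosses in order of increasing ray length, and the walk stops as
soon as the best hit lies closer than the entry of the current voxel.
Voxel size changes the speed, not the answer — the test suite checks
bit-equality of hits between voxel sizes, and equivalence with an
all-spheres brute-force oracle on thousands of random rays. Tangent rays
count as hits (closed spheres), a deterministic tie-break.

Single-helix maps use the same machinery after rotating the assembly so
the helix axis lies along z. The helix axis is the line through the
C$_\alpha$ centre of mass along the principal direction of the
C$_\alpha$ second-moment tensor with the *largest* principal moment, i.e.
the long axis of the C$_\alpha$ cloud. (Phrased via the mass-distribution
tensor rather than the mechanical inertia tensor, whose long axis carries
the *smallest* moment; the two phrasings pick the same line.) Contact
zones with neighbouring subunits mark every surface node whose hit point
lies strictly closer than 7 Å to any atom of the configured neighbour
residue range (654–692 for TRPV1).

### Pore radius

At each z the pore radius is the radius of the largest sphere, centred
anywhere in the plane orthogonal to the local axis tangent, touching no
van der Waals sphere. The centre search is a Nelder–Mead maximisation
seeded on the axis point plus a coarse 5×5 in-plane scan, with the centre
displacement capped (default 5 Å) so the probe cannot slip out of the
pore sideways; the reported radius is never worse than the best scanned
seed. Defaults: 0.25 Å z-step, 15 Å radius cap for locally unbounded
sections (flagged), atoms beyond 25 Å of the axis point ignored. Against
a dense brute-force grid search the optimiser agrees to better than
0.05 Å on random systems. $R_{gate}$ is the exact minimum over a gate
window, resolved from the configured gate residues' C$_\alpha$ z-span
± 3 Å; ties report the smallest z.

### 3D–1D environment scores

Residue environments follow the classic buried-area/polarity/secondary-
structure classification: side-chain buried area = reference accessibility
(the residue in an extended Gly-X-Gly tripeptide, computed with the same
radii, probe and sampling as the query — so the reference is always
consistent with the engine) minus observed accessibility in the full
assembly; the polar fraction is the area share of buried sphere samples
whose deepest blocker is N or O. Thresholds: exposed < 40 Å² buried,
partial 40–114 Å², buried ≥ 114 Å²; polar-fraction breaks 0.45/0.58
(buried) and 0.67 (partial); crossed with helix/sheet/other this gives 18
classes. Accessibility uses Shrake–Rupley sampling (1.4 Å probe, 242
deterministic Fibonacci-lattice samples per atom). Secondary structure
comes from backbone hydrogen bonds under the Kabsch–Sander electrostatic
criterion (amide H placed anti to the preceding carbonyl; bonds below
−0.5 kcal/mol), mapped minimally: turn bonds (i→i+3/4/5) cover helix,
long-range bonds mark sheet, the rest is other.

The per-residue score is a pure table lookup score(amino acid, class).
**The shipped score table is a synthetic surrogate, not the published
3D–1D table**: it is constructed from the united-atom side-chain logP
sums, side-chain polar capacity and secondary-structure propensities,
scaled to the familiar ±1 range, and ships as
`score3d1d_synthetic_v1.csv` with the construction documented in its
header. Every score output carries `score_table = "synthetic-v1"`
metadata; substituting a different table changes results and must remain
declared. The surrogate preserves the qualitative structure the
classification relies on (buried apolar environments favour Ile/Leu,
exposed ones favour Asn/Ser; helix-breaking penalties for Pro/Gly), and
all correlation machinery (pairwise Pearson R along the shipped
structure-based S6 alignment, TRPV1 670–687 ↔ TRPV3 −5 ↔ TRPV6 −104) is
table-agnostic. Cross-state correlations computed with the surrogate on
deposited structures will differ numerically from values computed with
the published table.

### Hydration and exposed surface area

The Connolly-style point cloud samples each atom's probe-expanded sphere
(probe 1.4 Å) on a shared deterministic lattice, rejects samples strictly
inside any other expanded sphere (probe-rolling rejection) and projects
survivors back to the van der Waals sphere; each point carries its atom's
sphere area divided by the sample count, so areas partition the surface
(an isolated sphere sums to $4\pi r^2$ within 2% by construction, exactly
for the lattice used). Water-exposed surface area (ESA) keeps points with
a water oxygen within 1.4 Å, restricted to the filter-to-gate axial
window resolved per frame from the boundary residues' mean C$_\alpha$ z
(G643–M682 for TRPV1 and the equivalent spans for TRPV3/TRPV6). Profiles
bin at 1 Å along z and 0.1 logP units along MHP; the hydrophobic share
ESA$_H$ counts points with MHP > 0. State differences are reported as
B − A; with equal replica counts the spread is the SD of paired
differences (so identical replica sets give exactly zero), otherwise the
per-state SDs propagate in quadrature. Water/ion densities are voxel
count averages (grid integral = mean particle count), and permeation
counts full crossings of a buffered gate interval (2 Å hysteresis beyond
each end suppresses boundary recrossing noise).

### π-bulge detection and state calls

A π-bulge is called when at least two consecutive residues accept an
i→i+5 backbone hydrogen bond under the DSSP energy criterion; the
reported interval is the span covered by those bonds. The state rule
table is deterministic: α-helical S6 → α-closed (or intermediate when the
gate is wide — the transitional "α-open" geometry); π-bulge with a wide
(≥ 2.0 Å) hydrated/conducting gate → π-open; π-bulge with a narrow
(≤ 1.5 Å) or demonstrably dry gate → π-closed; conflicting evidence →
intermediate. The 2.0/1.5 Å thresholds are heuristics bracketing the
reported open (≈2.8–2.9 Å) versus closed (≈0.5–1.3 Å) gate radii of TRPV
structures. Static-only calls (hydration/conduction unknown) fall back on
geometry and are flagged `static-only`; the package never claims to infer
conductance from a static structure.

## The synthetic test system

`make_c4_pore()` builds four ideal helices (NeRF chain extension, α
torsions −57/−47°, engineered π windows at −80/−55°, standard backbone
geometry) on a circle with exact 90° copies, with an Ile "gate" ring and
an Asn ring one turn above it by default — a minimal imitation of the
I679/N676 architecture of TRPV pores. The circle radius is calibrated by
fixed-point iteration so the minimal lumen radius hits the target within
0.1 Å. Side chains are extended stubs carrying the residue's real
heavy-atom composition (hence correct hydrophobicity typing) along the
C$_\alpha$→C$_\beta$ direction — not rotamers. `make_hydrated_frames()`
draws waters uniformly in the lumen cylinder at bulk number density
(0.033 Å⁻³ by default), optionally leaving a dry gate band, places ions
on the axis (or walks one through the gate), and jitters protein
coordinates with seeded Gaussian noise; frames are bit-reproducible for a
fixed seed.

What passing tests on this system do show: the field kernel, the
projection and tracing geometry, the area bookkeeping, the decomposition
identities, the detector logic and the rule table behave exactly as
specified. What they do not show: agreement with deposited TRPV
coordinates (side-chain packing, loop irregularity, real rotamers) or
with molecular-dynamics hydration statistics — those need real
structures and trajectories, which the package consumes but cannot
fabricate. Trajectory-scale quantities (ESA differences of hundreds of
Å², induced-MHP shares on MD ensembles) are therefore exercised as
identities and sign/trend checks on synthetic frames, not as value
reproductions.

## Numerical choices and degenerate inputs

- Hard MHP cutoff, closed-sphere ray hits, strict (<) 7 Å contact and
  inclusive (≤) 1.4 Å water criteria are all deterministic tie-breaks and
  are tested at their boundaries.
- Sphere sampling is lab-frame: areas are rotation-invariant only to
  sampling noise (≈0.1% of totals at 242 points/atom); environment
  *classes* and everything downstream of them are stable under rigid
  motion in the tests.
- Coincident duplicate atoms are deduplicated before surface generation
  (two identical spheres expose the area of one); altlocs resolve to the
  highest occupancy, first seen on ties.
- Axis rows with no surrounding atoms are flagged (radius capped, map row
  missed) rather than silently interpolated; profiles keep the flag.
- Profile sizes used by the default test and acceptance runs: ~570-atom
  four-helix pores, 0.25 Å radius steps, 6–10° angular steps, ≤ 8 frames,
  242-point spheres — chosen so the whole stack re-verifies in well under
  a minute while every identity is still exercised at full precision.

## Known limitations

- The 3D–1D score table is a documented surrogate (above); correlation
  *structure* is meaningful, absolute score values are not comparable to
  the published scale.
- The environment polar fraction attributes buried samples to their
  deepest blocker, one of several defensible operational readings of
  "area covered by polar atoms"; the choice is fixed and versioned.
- The radius optimiser is local by design (HOLE semantics); pathological
  non-convex sections wider than the displacement cap would need a larger
  cap, at the cost of possibly escaping the pore.
- Accessibility for environment scoring ignores crystallographic/frame
  waters by default (`include_waters = FALSE`), since deposited channel
  structures model few or none; the flag exists for trajectory use.
- The trajectory reader handles multi-model PDB (the text format the
  fixture writer emits); binary MD formats should be converted upstream.
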