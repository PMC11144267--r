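# poremapr

Quantitative "portraits" of ion-channel pores from structures and
trajectory frames, for structural biologists working on tetrameric
channels (TRPV and relatives) who need more than a radius profile to call
a state open or closed.

A narrow pore blocks ions when it dewets, and whether it dewets depends on
the chemistry of its walls, not just their geometry. `poremapr`
characterises the permeation pathway with four coupled descriptors:

- **Pore geometry** — HOLE-style radius profile: at each z the radius of
  the largest sphere, centred anywhere in the plane orthogonal to the
  local axis tangent, touching no van der Waals sphere; the gate minimum
  *R*<sub>gate</sub> is the exact minimum over the configured gate window.
- **Surface hydrophobicity** — the molecular hydrophobicity potential
  (MHP), the attenuated superposition of atomic logP contributions
  MHP(j) = Σ<sub>i</sub> *f*<sub>i</sub>·exp(−*r*<sub>ij</sub>/2) over
  atoms within 9 Å, ray-traced onto cylindrical projections of the van
  der Waals surface (3DDDA voxel-accelerated nearest-intersection
  tracing), and decomposed exactly into self + induced subunit
  contributions. Angular integration gives 1D profiles along the pore.
- **Residue packing** — 3D–1D environment scores per residue
  (buried-area / polar-fraction / secondary-structure classes from
  Shrake–Rupley accessibility and DSSP-style hydrogen bonds) and Pearson
  correlations of score profiles across states and channels along a
  shipped structure-based S6 alignment. The shipped score table is a
  documented synthetic surrogate; outputs carry its id in metadata.
- **Hydration** — Connolly-style surface point clouds with per-point
  areas and MHP, water-exposed surface area (ESA, with its MHP > 0
  hydrophobic share) over trajectory windows, water/ion density profiles,
  and permeation counting with hysteresis.

π-bulge detection (≥ 2 consecutive i→i+5 backbone hydrogen bonds) plus a
deterministic rule table label each structure `alpha_closed`, `pi_closed`,
`pi_open` or `intermediate`. Per-channel pore definitions for TRPV1/3/6
(axis residues, gate and filter residues, ESA regions, contact ranges,
alignment) ship as versioned data. A synthetic C4-symmetric pore generator
makes the entire stack testable offline.

Everything is tidyverse-native: structures, maps, clouds and profiles are
tibbles; results have `tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(poremapr)

pore    <- make_c4_pore(pore_spec(lumen_radius = 2.9, pi_window = c(12, 16)))
axis    <- build_pore_axis(pore, c(12, 15, 18))
profile <- radius_profile(pore, axis, z_step = 0.25)
glance(profile)
#> # A tibble: 1 × 3
#>   r_min z_min n_capped
#>   <dbl> <dbl>    <int>
#> 1  2.90  7.39        0

mhp_map <- trace_map(pore, axis, z_step = 0.5, angle_step = 5)
head(integrate_profile(mhp_map), 3)
#> # A tibble: 3 × 5
#>       z    self induced  total n_hit
#>   <dbl>   <dbl>   <dbl>  <dbl> <int>
#> 1  2.14 -0.0640  -0.225 -0.289    44
#> 2  2.64 -0.118   -0.177 -0.294    44
#> 3  3.14 -0.0989  -0.253 -0.351    44

detect_pi_bulge(pore, c(1, 22))
#> <helix_conformation> pi_bulge [residues 9-18]  (52 alpha / 20 pi bonds)

cfg <- list(axis_residues = c(12, 15, 18),
            gate_region_residues = c(14, 16), s6_range = c(1, 22))
glance(classify_structure(pore, cfg))
#> # A tibble: 1 × 4
#>   label   confidence  r_gate s6_conformation
#>   <chr>   <chr>        <dbl> <chr>
#> 1 pi_open static-only   2.90 pi_bulge

frames <- make_hydrated_frames(pore, n_frames = 4, seed = 1)
esa_profile(frames, region = c(2, 9))
#> <esa_profile> 4 frames, region z = [2.0, 9.0]: ESA_T = 15.9 A^2, ESA_H = 15.9 A^2
```

The pore was built with a 2.9 Å lumen and an engineered π-window: the
radius profile recovers 2.90 Å, the detector finds the i→i+5 bonded
stretch, and the rule table calls the state `pi_open` (flagged
`static-only`, since no trajectory evidence was supplied). The negative
`total` MHP values at the extracellular end come from the Asn ring above
the Ile gate; the `induced` column shows how much of the wall's character
is contributed by neighbouring subunits. The ESA printout gives the
water-contacted surface between the chosen axial bounds, total and
hydrophobic (MHP > 0).

For real structures, `channel_config("trpv1")` (or `"trpv3"`, `"trpv6"`)
supplies the axis/gate/filter residue definitions, and
`inst/cli/poremap-tool.R` wraps the same functions as shell subcommands
(`radius`, `map`, `profile`, `score`, `classify`, `esa`, `density`,
`fixtures`).

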