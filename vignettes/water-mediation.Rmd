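---
title: "Structured waters in quadruplex-ligand binding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured waters in quadruplex-ligand binding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqwater)
```

## The problem

Crystal structures of small molecules bound to G-quadruplex (GQ) DNA show
that much of the "binding" is not direct: ordered water molecules sit in the
grooves and at the quartet faces and hydrogen-bond simultaneously to ligand
side chains and to the DNA backbone or base edges. gqwater turns that
observation into a reproducible pipeline: detect hydrogen bonds under
explicit geometric criteria, build the ligand-water-DNA contact network,
enumerate bridging water chains, classify hydration shells and clusters,
convert B factors to displacements, and identify waters conserved between
two structures after superposing their G-quartets.

## Hydrogen-bond model

A contact is accepted when the donor-acceptor distance is at or below
`max_distance` (default 3.25 Å) and, where an angle test applies, the
angular deviation from ideality is at most `max_angle_deviation` (default
30°). Crystal structures at the 1.1-2.5 Å resolutions this package targets
do not resolve hydrogens, so the donor-hydrogen...acceptor rule cannot be
applied literally. Three modes are provided:

* **antecedent_proxy** (default): the angle antecedent-donor-acceptor must
  lie within the deviation cutoff of the donor's ideal valence angle (120°
  for sp2 nitrogens such as base amino/imino groups, 109.5° for sp3). This
  is fully deterministic and needs no hydrogen construction.
* **ideal_hydrogen**: an idealized hydrogen is placed 1.0 Å from the donor,
  coplanar with antecedent, donor and acceptor at the ideal
  antecedent-donor-hydrogen angle on the acceptor's side, and the deviation
  of donor-H...acceptor from linearity is tested. This is the closest
  hydrogen-free reading of the literal rule; it is slightly more permissive
  near ring planes.
* **distance_only**: no angle test.

Waters are exempt from any angle test in every mode: a water oxygen is a
free rotor with no fixed antecedent, and applying a donor-geometry rule to
it would reject essentially every water-mediated contact the analysis
exists to find. Donors without configured antecedents (e.g. ligand atoms
supplied without neighbor information) are likewise exempt rather than
silently rejected.

Two criteria presets are exposed. The default (3.25 Å) is the screening
rule used to select structures. The `"published"` preset (3.45 Å,
distance-only) exists because published contact tables for these complexes
list interactions out to 3.4 Å; reproducing a printed table and screening a
structure are different tasks, and the package does not guess which cutoff
a printed 3.3-3.4 Å contact "should" have satisfied. Neighbor search is an
exact all-pairs computation; results are required (and tested) to be
identical to a brute-force scan.

## Roles

Donor/acceptor roles for DNA are built in: guanine N1/N2 donors and
O6/N3/N7 acceptors, adenine N6 donor and N1/N3/N7 acceptors, thymine N3
donor and O2/O4 acceptors, cytosine N4 donor and O2/N3 acceptors, plus the
backbone oxygens OP1/OP2/O4'/O5'/O3' as acceptors. Ligand atoms only ever
receive roles from an explicit override table (`mm41_role_overrides()` et
al.); nothing is inferred from ligand chemistry, because protonation states
of morpholino and piperazine nitrogens are an assumption the user should
make visibly, not one the code should hide. The packaged MM41 table treats
the basic side-chain ring nitrogens as donors (they are presumed protonated
at physiological pH) and the chromophore carbonyl oxygens as acceptors, so
water bridges to the chromophore count as ligand-mediating contacts.

## Network stage

The hydrogen-bond set is an undirected graph over polar atoms. On it the
package computes:

* **Bridges**: simple paths ligand atom → water^k → DNA atom with
  1 ≤ k ≤ `max_waters`. The default depth 4 matches the longest mediating
  chain observed in the packaged tables (a linear cluster of four waters
  extending from a morpholino nitrogen). Paths never repeat a water; ties
  in the output ordering break lexicographically.
* **Shells**: first (bonded to any non-water), second (bonded only to
  first-shell waters), bulk-like (the rest). The labels partition the water
  set by construction.
* **Clusters**: connected components of the water-water subgraph, each
  with its anchors (the non-water atoms the component touches). Singletons
  count as clusters.
* **Mediation summary**: the number of direct ligand-DNA hydrogen bonds,
  the number of distinct ligand atoms contacting at least one water, and
  the number with a complete bridge to DNA. Mediation is counted over
  *ligand atoms*, not bonds or paths: a printed table can contain a
  ligand-bound water whose DNA partner is unresolved (W56 in the packaged
  BRACO19 table), and atom-level water adjacency is the statistic that
  remains well-defined in that case.

Groove labels (groove 1-4) are annotations carried from the input tables
or supplied by configuration. They are never computed: groove assignment in
the source structures was done by inspection and no algorithm is defined
for it.

## Mobility

`b_to_u()` implements `<U> = sqrt(B / (8 * pi^2))` with B in Å² and `<U>`
in Å. For a group of atoms, the quoted `<U>` is computed from the group's
*mean B* (`u_of_mean_b`), not as the mean of per-atom displacements; both
are reported, but the mean-B convention is what reproduces quoted pairings
such as B = 51 Å² → `<U>` = 0.8 Å exactly. Reports round B means to
integers and displacements to one decimal, the conventional precision.

## Superposition and conserved waters

`fit_quartets()` performs a least-squares rigid superposition (Kabsch, via
SVD with a determinant correction so the rotation is always proper) on the
eleven guanine base heavy atoms of an explicit residue correspondence.
The base atoms are used because the quartet planes are the conserved
scaffold; backbone and loop atoms flex between native and complexed forms.
All quartet guanines in the correspondence are fitted — when in doubt, fit
the whole core. The correspondence itself is always explicit input, never a
sequence alignment: which guanine overlays which is a topology-dependent
scientific choice.

Conserved waters are mutual nearest neighbors among (transformed A waters)
× (B waters) within a threshold, default 1.0 Å — the conventional criterion
for two crystallographic waters occupying the same site. Mutual-NN is
deterministic and guarantees each water joins at most one pair; a greedy
ascending-distance sweep is available as an alternative. A globally optimal
assignment is not offered.

Degenerate fits (fewer than three pairs, or a collinear atom set detected
from the second singular value) are errors, not warnings.

## Synthetic scenes

`generate_scene()` builds fully ground-truthed test structures: planar
idealized guanines (hexagon-pentagon geometry, 1.39 Å bonds, real atom
names so the production role tables apply unmodified) arranged as 4-fold
quartets stacked 3.4 Å apart, perimeter phosphate oxygens, a ligand layer
3.6 Å above the top quartet, planted water bridges, and decoy waters.

Numerical choices that make truth exact rather than probable:

* Planted chains rise steeply (70.5° elevation) so the ligand-donor proxy
  angle is exactly ideal, and chains in different grooves stay several
  angstroms apart.
* Bond-length jitter is a truncated Gaussian capped so no planted edge
  exceeds 3.2 Å; recovery under the default 3.25 Å cutoff is therefore a
  construction guarantee. An uncapped Gaussian at sd 0.15 Å would
  occasionally cross the cutoff and make "100% recovery over 50 seeds" a
  coin flip rather than a property.
* Decoys are rejection-sampled to clear 3.25 + 0.5 Å from every atom
  including other decoys, so they form no bonds and appear only as
  bulk-like singletons. Placement failure after 500 tries is an error
  naming the constraint.
* `derive_native_copy()` caps conserved-water jitter at a 0.9 Å norm
  (inside the 1.0 Å matching threshold) and places fresh decoys at least
  1.5 Å from the mapped position of every original water, so the planted
  conserved-pair list is exactly the recoverable one.
* Each scene draws from a single RNG stream seeded by `spec$seed`, and the
  generator restores the caller's RNG state.

Default B factors (nucleotide 25 ± 5, ligand 51 ± 8, water 30 ± 3 Å²)
reflect typical refined values for such complexes around 2 Å resolution,
with ligand side chains more mobile than the bound waters.

One documented convention: "jitter sd σ" means an isotropic Gaussian with
sd σ per coordinate. A copy jittered this way on one side superposes with
an expected RMSD of σ·sqrt(3 − 6/n), which the Monte-Carlo test asserts.

What the scenes deliberately do *not* emulate: helical twist, the ion
channel, sugar-phosphate connectivity, realistic packing density, or
crystallographic symmetry. Passing tests show the detection, network,
mobility and superposition machinery is correct on geometry with known
truth; they do not validate, for example, altloc handling on messy real
deposits beyond what the parser tests cover, or groove assignment, which is
not computed at all.

## Structure acceptance and I/O

Structures are screened with resolution ≤ 2.5 Å and (by default) at least
one ligand-water hydrogen bond; a missing resolution is an explicit
rejection reason. PDB (and mmCIF) parsing is delegated to bio3d; gqwater
resolves alternate locations by keeping the highest-occupancy conformer
(ties go to the alphabetically first altloc code), uses model 1 of
multi-model files, and drops hydrogens unless asked to keep them. Waters
are recognized by residue code (HOH/WAT/DOD by default) and must have
exactly one heavy atom; ions are categorized separately from waters, so
water counts never silently include potassium. Round trips through
`write_structure()`/`read_structure()` preserve coordinates to 3 decimals
and B factors to 2 (the PDB fixed-column precision).

## Problem sizes

The test suite and the acceptance script run on scenes of roughly 100-250
atoms, 50-seed recovery loops, and the two packaged contact tables (17 and
14 bonds). These sizes exercise every code path — all-pairs detection
against a brute-force oracle, exhaustive path enumeration, Monte-Carlo RMSD
statistics — while keeping a full run around a minute.

## Known limitations

* The angle criterion without hydrogens is necessarily an interpretation;
  both interpretations are implemented, but neither is "the" literal rule.
* Mediation counting by distinct ligand atoms is one of several defensible
  conventions; the per-atom detail table is emitted so any other convention
  can be recomputed from it.
* No crystallographic symmetry expansion: contacts to symmetry mates are
  invisible unless the input file already contains the expanded assembly.
* No energetics: the package counts and measures hydrogen bonds; it does
  not score water displaceability or binding contributions.
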