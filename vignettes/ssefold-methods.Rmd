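---
title: "RNA 3D structure assembly from smallest secondary elements: methods and design"
author: "ssefold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ssefold methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`ssefold` predicts RNA tertiary structure from a sequence and its secondary
structure. The method rests on a simple observation: an RNA secondary
structure decomposes uniquely into *smallest secondary elements* (SSEs) —
stems (helices), hairpin loops, bulge loops, internal loops and junction
(multi-branch) loops — and the 3D conformation of each element is largely
transferable between molecules. The pipeline therefore:

1. parses the dot-bracket input, separates pseudoknot pairs (pairs that
   cross the nesting) from the nested structure, and decomposes the nested
   part into a rooted SSE tree;
2. finds a 3D template for every tree node in a shape-indexed template
   library, ranked by sequence identity;
3. assembles the templates into a full model by walking the tree and
   superposing each child template onto its parent over the atoms of their
   shared closing base pairs (Kabsch superposition);
4. optionally samples alternative templates, and optionally refines models
   by restraint-guided simulated-annealing Monte Carlo (SAMC) in which
   pseudoknot base pairs act as distance restraints;
5. clusters the resulting ensemble by pairwise RMSD with a k-medoid rule
   and ranks cluster centroids with a knowledge-based score.

Missing loop templates are generated de novo, either by a bi-residue
fragment method or by distance geometry.

## Secondary-structure handling

Pairs are matched per bracket alphabet (`()`, `[]`, `{}`, `<>`, then
`Aa`..`Zz`), pooled, and split by an exact interval dynamic program that
keeps a maximum-cardinality crossing-free subset as the nested structure;
everything else becomes a pseudoknot pair. Ties between equally large
crossing-free subsets are broken in favour of the pair whose opening
position is most 5' — the choice is arbitrary but deterministic, which the
rest of the pipeline requires.

Loop nodes carry up to two closing pairs per adjoining helix end (one for
length-1 helices). These shared pairs are what makes assembly well-posed:
consecutive templates overlap in at least two base pairs (roughly 60
atoms), so the superposition is never under-determined. The tree root is
the SSE containing the 5'-terminal residue; when the molecule does not
begin and end in a single outermost helix, an *exterior* node (a kind not
always distinguished in loop taxonomies) holds the dangling termini and
single-stranded linkers between top-level helices. Isolated length-1
helices are kept as stems rather than absorbed into loops; both
conventions appear in the literature and the choice only moves one pair of
residues between neighbouring templates.

*Movable elements* are the contiguous spans whose rigid motion cannot tear
a helix: for every maximal helix, the span must contain both strands
entirely or not at all. This predicate is evaluated at helix granularity,
not pair granularity, so a span can never separate stacked pairs of the
same stem. A direct consequence is that rigid moves of movable elements
leave every nested base pair geometrically intact, which is exactly the
secondary-structure-preservation property the optimizer relies on.

## Synthetic nucleotide geometry

The package ships no experimental coordinates. All fixtures derive from an
idealized nucleotide geometry constructed once (see `R/nucgeom-data.R`):
planar base rings as regular polygons, a Watson-Crick pair frame with the
C1'-C1' distance at 10.4 Å and glycosidic bonds at 54.5°, and a
sugar-phosphate backbone placed by trilateration from ideal bond lengths
and 1-3 distances, with the phosphate solved so that the A-form helical
step operator (twist 32.7°, rise 2.81 Å) closes the O3'(i)-P(i+1) bond at
exactly 1.60 Å on both strands. The representation is a reduced heavy-atom
set: nine sugar/phosphate atoms plus the base ring nitrogens and carbons
(15 atoms per pyrimidine, 18 per purine). Exocyclic substituents, O2' and
the phosphate oxygens are omitted; every consumer of the geometry
(annotation, scoring, restraints) is defined on the reduced set, and
externally read PDB files keep whatever atoms they have.

What this geometry does *not* emulate: sequence-dependent helical
parameters, base-pair propeller/inclination, sugar pucker diversity, and
non-canonical pairs. Tests passing on these fixtures therefore demonstrate
the correctness of the pipeline's logic (decomposition, superposition,
sampling, clustering, restraint satisfaction), not prediction accuracy on
experimental structures — for that, harvest a template library from real
coordinate files with `harvestTemplates()`.

## Template library

Templates are indexed by exact shape: SSE kind plus the ordered per-strand
residue counts, closing residues included. Near-length matches are not
admitted; a missing shape falls back to de novo loop generation. Within a
shape, candidates are ranked by the fraction of identical sequence
positions over all strands, with ties broken by source id and insertion
order so that ranking is a total order independent of library build order.
The first prediction uses the top-ranked template of every node; further
predictions draw templates at random under a caller-supplied seed.

The synthetic fixture library (`buildFixtureLibrary()`) answers every stem
query with an ideal A-form helix carrying the query's own sequence and
every loop query with a bi-residue-generated loop. Because identical
helices with different sequences would be redundant, stems are built
per-sequence on demand rather than enumerated.

## De novo loop generation

**Bi-residue method.** A source structure is cut into overlapping
two-nucleotide fragments; each fragment stores the rigid transform between
its residues' sugar frames. A loop is built by chaining fragments: the
closing pairs of each helix end form rigid ideal-helix blocks, the parent
end is fixed, and each strand of unpaired residues grows from it by
randomly chosen fragments, with child helix ends riding on the chain.
Fragment replacements are accepted by the Metropolis rule under a
geometric cooling schedule (default 20 → 0.05 over the step count) against
an energy with three terms: chain closure at the parent's far end,
covalent-junction quality, and steric overlap (including two "phantom"
helix-continuation pairs per end, so loops do not thread through the stems
they will be attached to). After the fragment search, cyclic coordinate
descent (CCD) closes the chain exactly: rigid rotations of the sub-chain
about free-residue phosphates preserve every internal bond length while
steering the final O3' onto its 1.60 Å bond. The default fragment source
is a seeded synthetic chain walked in segments of constant curvature (up
to ~75°/step, the sharpness of tight RNA turns), with collision rejection;
any conformation — e.g. a real 5S rRNA file — can be supplied instead.

**Distance geometry.** Distance bounds are collected per atom-pair class —
within a nucleotide, between adjacent nucleotides, between paired
nucleotides, between stacked nucleotides — as observed min/max (or 1st/99th
percentiles) over annotated structures. For a query loop the bounds
matrices are triangle-smoothed (Floyd-Warshall), a distance matrix is
sampled uniformly between the bounds, embedded by the classical
metric-matrix eigendecomposition (top three eigenvectors, via
`stats::cmdscale`), and refined against the original bounds by L-BFGS on
the violation stress. The mirror ambiguity inherent to embedding is
resolved by the handedness of the sugar ring (signed volume of
C1'-C2'-C3'-C4'); with exact consistent bounds the reconstruction is exact
to numerical precision, which is the test anchoring this module.

## Assembly and relaxation

Assembly walks the tree in pre-order. Each template is mapped onto its
node's residues, its base rings are rebuilt on the placed sugars where the
template sequence differs from the target, and the fragment is superposed
onto the already-placed structure over all atoms of the shared closing
pairs; duplicated residues keep the parent's copy. Re-assembly during
template sampling recomputes the whole structure rather than only the
changed subtree — at the sizes where sampling is used the full
re-assembly is milliseconds, and one code path is easier to keep correct.

`relaxConformation()` is a deliberately simple geometric cleanup (an
external force-field minimisation is out of scope): per-residue rigid
translations iteratively restore out-of-window O3'-P junctions, relieve
clashes (rejecting any pass that increases the clash count), and hold
secondary-structure pairs inside Watson-Crick windows, with a final
bonds-only sweep so clash relief can never leave a torn junction.

## Optimization under restraints

The optimizer energy is a weighted sum of squared flat-bottom violations:

* junction bonds, window 1.35–1.90 Å (weight 10);
* soft-sphere clashes on a reduced atom set (P, C4', C1'), radius 3.0 Å
  (weight 1);
* nested-pair maintenance, C1'-C1' 9.0–11.5 Å and WC-edge N-N 2.3–3.5 Å
  (weight 5);
* restraints (weight 10, times the per-restraint weight);
* optionally the knowledge-based score (weight 0 by default — scoring is
  used for post-ranking, keeping the Monte Carlo energy cheap and local).

A base-pair restraint (the pseudoknot realisation, and `PAIR` records in
restraint files) is a C1'-C1' window of 10.4 ± 1.5 Å plus a WC-edge N-N
window of 2.8 ± 0.8 Å, both bracketing the package's ideal helix geometry.
`DIST` records carry explicit C1'-C1' bounds. The top-N rule for
coevolution-derived contacts keeps `floor(0.2 × length)` restraints;
0.2 × 75 = 15 for the canonical 75-nt example. Flooring was chosen over
rounding: it never admits a restraint the budget does not cover.

Each SAMC step picks a uniformly random movable element and one of three
rigid moves — translation (σ = 2 Å), rotation about the element centroid,
or rotation about the anchor axis (σ = 15°) — scaled by √(T/T_high), and
accepts with min(1, exp(−ΔE/T)). The schedule heats from T_low = 0.02 to
T_high = 2 over 10 geometric rungs and cools back over 25 rungs with 150
proposals per rung. The asymmetric schedule is deliberate: heating only
needs to unlock the starting basin, while the junction bonds stretched by
high-temperature moves need a slow cooling tail to anneal back into their
windows. One conformation per rung is recorded (capped at 1000), and the
best-energy conformation is tracked separately.

On the packaged 28-nt H-type pseudoknot system, the nested-only assembly
starts roughly 12 Å from the restraint-satisfying reference; optimization
with the three pseudoknot restraints halves the median RMSD relative to
optimization without them and satisfies every restraint, which is the
package's acceptance check for the pseudoknot mechanism (numbers are
recomputed by `scripts/acceptance.R` and the test suite, not quoted here).

## Clustering and scoring

Clustering is k-means on the pairwise RMSD matrix where the "mean" of a
cluster is its medoid under the explicit rule: the member with the
smallest sum of distances to all other members, ties to the smallest
index. Initial centroids come from farthest-point seeding off a seeded
random start; assignment and centroid update iterate to a fixed point, and
the within-cluster distance sum is monitored to be non-increasing. Every
converged centroid is verified against exhaustive search in the tests.

The knowledge-based score is a documented *variant*, not a reproduction of
any published potential: distance-binned (0.5 Å bins to 20 Å) pairwise
pseudo-energies over five coarse atom types (P, C4', C1', glycosidic N,
WC-edge N) as the log-ratio of observed to pooled type-blind reference
frequencies, plus backbone pseudo-torsion (eta/theta) terms against a
uniform reference, all capped to [−4, 6]. The shipped default trains on
synthetic fixtures at first use; it separates native fixtures from
scrambled decoys and is rigid-motion invariant, but for experimental work
it should be retrained on a curated structure set with
`trainPotential()`.

Interaction annotation is geometric: canonical pairs require
complementarity (incl. G-U), WC-edge N-N distance 2.3–3.5 Å, C1'-C1'
9.0–11.5 Å and base-plane angle < 30°; stacking requires base-centroid
distance < 5.5 Å and plane angle < 30°. INF is the standard
√(PPV × STY) with the conventions: both sets empty → 1, exactly one
empty → 0.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
fixtures: a 16-nt hairpin, a 24-nt internal loop, a 38-nt three-way
junction, the 28-nt pseudoknot system (10 optimization seeds per arm), a
40-member decoy ensemble for 50 clustering runs, and one ~1750-nt
multi-junction assembly. Every stochastic routine takes an explicit seed
and restores the caller's RNG state; equal seeds give bit-identical
libraries, trajectories and manifests.

## Known limitations

* The idealized geometry omits exocyclic atoms and sequence-dependent
  helix shape; predictions on real RNAs require a harvested library.
* The bi-residue loop search is a single-replacement Metropolis walk; for
  long junction strands the CCD closure guarantees connectivity but loop
  conformations remain coarse, and generated loops may retain a few mild
  steric contacts (the relaxation pass reduces them).
* Non-canonical pair families are not annotated, and INF is computed for
  canonical pairs and stacking only.
* The optimizer moves rigid elements; it cannot repack loop internal
  geometry, which bounds how far refinement can travel from the assembled
  templates.
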