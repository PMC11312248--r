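---
title: "Shape-focused pharmacophore modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-focused pharmacophore modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShapePharm)
```

# The model

ShapePharm turns an ensemble of flexibly docked active-ligand poses into a
compact pseudo-ligand — a *shape-focused pharmacophore model* — and uses it
as a 3D template for similarity-based virtual screening. The underlying
assumption is that true actives, docked into the same cavity, place
chemically similar atoms at recurring positions (hotspots), while the
placement of decoy atoms is incoherent. Clustering the overlapping
same-type atoms of the ensemble and keeping the cluster centroids yields a
model that (a) traces the cavity's occupied volume and (b) weights the
consensus hotspots, since several centroid atoms of different types can
still co-locate.

## Input preparation

The modeling input is a set of MOL2 pose entries, usually the best pose of
each of the top-ranked active ligands (`selectTopActives()`, default 50
ligands, one best pose each; score ties break lexicographically by ligand
id so the selection is reproducible under input shuffling). Non-polar
hydrogens — those bonded to carbon — are removed; polar hydrogens (on
N/O/S) are kept because they carry hydrogen-bonding information. When an
entry carries no bond records the nearest heavy atom within 1.2 Å
classifies each hydrogen, which keeps the operation total on bond-free
input; unclassifiable hydrogens are retained with a warning rather than
silently dropped. Entries are then merged into a single bond-free point
cloud with per-atom provenance. Optionally, the cloud (or the finished
model) is limited to atoms within 2.0 Å of the nearest *heavy* atom of a
reference ligand; nearest-atom distance is used rather than a centroid
distance so the pocket envelope follows the reference's shape. Limiting
before or after modeling are both exposed and neither is preferred by
default, as the two orders answer slightly different questions (trim the
evidence vs. trim the summary).

## Clustering

Atoms cluster only with atoms of the same *effective* type. By default the
effective type is the Sybyl type; similar-type groups (e.g. `C.2`+`C.3`)
can be declared so listed types co-cluster, in which case the group uses
the largest member cutoff and the output atom is labeled with the dominant
original type.

The per-type search radius `MAX` comes from a versioned constant table of
GAFF reference bond lengths reduced by 5%, the reduction keeping the
radius just under a covalent bond so that chemically bonded neighbors of
the *same* molecule do not collapse into one another while genuinely
superimposed atoms of *different* poses do. All aromatic (`.ar`) types use
the fixed radius 1.38 Å — the aromatic C–C bond length — instead; `N.pl3`
is trigonal planar but not aromatic and keeps its own derived radius.
Types missing from the table fall back to a global cutoff (default 1.0 Å,
an intentionally conservative sub-bond value for unknown chemistry); a
JSON override file always wins, including for aromatic types.

Two engines share this radius table:

* **Greedy shortest-pair merging** (default). Per type, the globally
  closest pair of current items (atoms or clusters) merges if within
  `MAX`; a cluster is represented by its running centroid. Measuring from
  the running centroid rather than from original members is a deliberate
  interpretation — the cluster "is replaced" by its centroid — and it
  guarantees termination, since a merge strictly reduces the item count.
  Distance ties break by the smaller first item index, then the smaller
  second index, making the partition deterministic; for generic input the
  result is also invariant to atom order and to rigid motions of the
  cloud (both are tested).
* **Markov clustering** (`method = "mcl"`). Edges connect same-type pairs
  within `MAX`, weighted `MAX² − d²` (non-negative, zero exactly at the
  cutoff), exportable in the whitespace `ABC` format. The MCL process is
  implemented natively in dense matrix arithmetic: self-loops with the
  node's maximum incident weight, column normalization, then alternating
  expansion (matrix squaring) and inflation (entrywise power, renormalize)
  with pruning of entries below 1e-6, until the matrix changes by less
  than 1e-8 or 200 iterations (non-convergence returns the current
  partition with a warning — it has not been observed in testing).
  Clusters are the connected components of the converged matrix's nonzero
  structure, so disconnected atoms always end up separated and isolated
  atoms are singletons. The run is fully deterministic and a thread-count
  argument is accepted for interface compatibility only: the partition is
  identical for any value. Raising the inflation exponent (default 2)
  sharpens the transition distribution; in practice partitions refine as
  inflation grows, and the test suite asserts the cluster count never
  decreases across inflation 2 → 20. Exact subset refinement between
  consecutive inflation values is typical but not an invariant of the
  algorithm, so it is not asserted.

Each cluster becomes one model atom: position = member mean, type = most
frequent member type (lexicographic tie-break), charge = the member charge
of largest magnitude ("biggest difference against zero"; an exact
magnitude tie takes the lower-index member), with the cluster size kept as
provenance.

## Post-filters

Filters apply in the fixed order `deletetypes` → `clustermin` →
`clusterminchr` → negative-image conversion; the order is recorded in the
model's settings fingerprint because the composition is not commutative
(e.g. charged-atom pruning reads the pre-conversion charges). The choice
to run `clusterminchr` *before* charge rewriting is a design decision: the
filter is meant to judge the evidence (how many input atoms supported a
charged hotspot), which the rewritten ±threshold charges no longer convey.

* `clustermin` *n* drops model atoms whose cluster had fewer than *n*
  members — the consensus filter.
* `clusterminchr` *n* does the same only for charged atoms, where
  "charged" means |q| strictly above the `nibthreshold` (default 0.2 e).
  Strictness matters: boundary atoms count as neutral, matching the
  neutral default class of the conversion below.
* `deletetypes` removes whole Sybyl types (dummy atoms etc.).
* Negative-image conversion recodes every atom by charge class: positive →
  `N.3`, negative → `O.3`, neutral → `C.ar` if originally aromatic else
  `C.3`; charges become +threshold / −threshold / 0 unless the original
  charges are explicitly kept. Re-applying the conversion with identical
  settings is a recorded no-op, which keeps the operation idempotent even
  though the rewritten boundary charges would otherwise reclassify under
  the strict threshold.

# Similarity scoring

The scorer follows the published contract of shape/ESP comparison tools:
scores in [0, 1] with 1 a perfect match, a default 50/50 shape/ESP
weighting, a shape-only (100/0) mode, and a fixed-pose mode versus an
alignment-optimizing mode. The internal formulas are this package's own:

* **Shape**: every atom is an isotropic Gaussian whose volume matches its
  hard van-der-Waals sphere (fixed per-element radii, C 1.70 … I 1.98 Å;
  unknown elements use carbon's). The score is the Gaussian-overlap
  Tanimoto `O_ab / (O_aa + O_bb − O_ab)`. It is symmetric, jointly
  rigid-motion invariant, 1 for identical sets, and decays to 0 with
  separation; a two-atom closed form is verified analytically in the
  tests.
* **ESP**: partial charges are smoothed by the same Gaussians; the
  normalized cross-correlation `c ∈ [−1, 1]` of the two charge fields maps
  to `(1 + c)/2`. Identical charged sets score 1, sign-flipped charges 0,
  and an all-neutral comparison returns the uninformative convention 0.5
  (so neutral models neither reward nor punish). Note the mapping scores
  *correlation*, not proximity: two far-apart charge sets are
  uncorrelated (0.5), and the "no match" limit of the combined score is
  carried by the shape term.
* **Combined**: `w·shape + (1−w)·esp`, default `w = 0.5`; `w = 1`
  reproduces the shape component exactly.

Because the scorer is bespoke, absolute values are not comparable with any
external program's; all claims in this package rest on the contract,
orderings, and enrichment behavior.

**Rescoring** scores docked poses in place and reduces multiple poses of a
ligand to the maximum score (best-pose aggregation, the standard choice
when a docking run yields several predictions per ligand; a first-pose
mode is exposed). **Rigid docking** searches rigid-body placements per
conformer: starts are the four proper axis-sign combinations of
principal-axes superposition (optionally also inertia-order swaps) *plus
the original placement*, each refined by a deterministic derivative-free
coordinate search over the six rigid-motion parameters (initial steps
0.5 Å / 0.2 rad, step halving, score tolerance 1e-4, at most 500
evaluations per start). Including the identity start makes the aligned
score ≥ the fixed-pose score by construction. Conformers with a
degenerate (collinear) inertia tensor fall back to centroid alignment
plus a coarse rotation grid.

# Enrichment metrics

* **AUC** is the Mann–Whitney statistic over active/decoy pairs with ties
  credited 0.5, with the Hanley–McNeil (Wilcoxon) standard error.
* **EFd** at decoy fraction *f*% walks the descending ranking until
  `ceiling(f/100 · n_decoys)` decoys have been met and reports the
  true-positive rate (%) at that depth. The ceiling (rather than floor)
  keeps the smallest fractions meaningful for small decoy sets.
* **BEDROC** follows the Truchon–Bailey normalization of the exponentially
  weighted active-rank sum; α = 20 (weighting roughly the top 8%) is the
  default, and the value approaches the AUC as α → 0 (checked
  numerically).
* **ROC curves** advance diagonally through tied scores, so the
  trapezoidal area equals the tie-credited AUC exactly; the semilog export
  clamps the first false-positive rate to `1/n_decoys`.

Tied scores rank actives *last* for EFd and BEDROC — the pessimistic
convention, chosen so reported enrichment never benefits from ties (AUC
keeps the standard 0.5 credit, which its pair-counting definition
requires). All metrics are invariant under strictly monotone score
transforms.

# Greedy model optimization

Backward elimination over model atoms: every generation rescores the
training set once per candidate single-atom deletion and adopts the
strictly best improvement of the target metric (BEDROC α = 20 by default;
AUC and EFd are selectable since the target metric is a choice, and the
choice is recorded in the trace). "Strictly" means an improvement larger
than 1e-12, a floating-point-safe termination rule; improvement ties take
the lowest atom id. The search stops when no deletion improves or the
model reaches the `minAtoms` floor (default 3, preventing degenerate
one-atom models; realistic models stay far above it). The trace records
every generation and replaying it from the initial model reproduces the
final model exactly. Candidate evaluations are independent, so the scan
could be parallelized without changing results; the implementation
evaluates them sequentially in atom order, which *is* the documented
tie-break order.

# The synthetic benchmark

The generator emulates the statistical structure the method assumes, not
chemistry. Hotspot *anchors* (default 10) are typed, charged points with
minimum separation 2.5 Å — comfortably above every clustering radius, so
distinct anchors cannot merge — in a 12 Å box, a typical binding-site
scale. A default 30% of anchors are charged (|q| in 0.3–0.6 e, the range
of strong partial charges on polar groups; positive anchors are typed
`N.3`, negative `O.3`), the rest near-neutral common types. Each of the
default 50 *actives* places one atom of the anchor's type at a random 80%
subset of anchors with isotropic 0.3 Å Gaussian jitter — the scale of
pose-to-pose variation among well-docked actives — plus 2–6 random `C.3`
"linker" atoms kept 2 Å off the anchors; charges inherit the anchor's
with 0.05 e noise. *Decoys* (default 500, a 1:10 ratio) draw their atom
counts and (type, charge) pairs from the actives' pools but place atoms
uniformly in the box: property-matched in composition, structureless in
geometry. Labels are split 70/30 train/test, stratified by class, and a
single seed reproduces everything bit-for-bit (the manifest records every
parameter).

What the generator does *not* emulate — covalent geometry, conformational
strain, chemically realistic decoys, protein sterics — bounds what passing
tests show: they validate the clustering, scoring, metric, and
optimization machinery under the method's own assumptions, not performance
on real screening data. Under the default conditions the benchmark is
deliberately an easy discrimination task (model-based rescoring reaches
test AUC above 0.8 while random scoring stays near 0.5, as the acceptance
suite verifies on ten seeds); the optimization tests therefore also use a
hand-built fixture with a planted decoy-overlapping model atom, where the
first greedy deletion is forced and checked against an exhaustive
single-deletion scan.

# Problem sizes and numerical conventions

The test suite runs at desk scale by design: oracle-equivalence checks use
200 random clouds of at most 30 atoms against an exhaustive
matrix-rescan oracle; anchor-recovery and screening properties use 50
actives / 500 decoys over 10 seeds; optimization fixtures use 20/80
compound screens with 9-atom models. Coordinates are Angstrom everywhere,
charges elementary units, and MOL2 output carries 4 decimals — the
round-trip tests compare at that precision. Degenerate inputs have defined
behavior throughout: empty clouds, models emptied by a filter, one-class
rankings, collinear conformers, and unclassifiable hydrogens all raise
informative errors or warnings rather than propagating nonsense.

# Known limitations

* Scores are not comparable across scorers; only orderings matter.
* The greedy cluster centroid depends on merge order in near-tie
  configurations; the documented tie-break makes it deterministic but not
  order-free in the degenerate case.
* The ESP term uses smoothed point charges, not a Poisson–Boltzmann
  field, and is uninformative (0.5) for neutral models.
* Rigid docking's local search is deterministic but not globally optimal;
  hard multimodal alignment cases may need more starts (inertia-order
  swaps are available behind a flag).
* Greedy optimization can overfit small training sets — the trace makes
  each accepted deletion auditable, and the held-out metrics in the
  pipeline report are the guard.
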