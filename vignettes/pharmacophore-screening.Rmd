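---
title: "Receptor-based pharmacophore screening: models, matching and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-based pharmacophore screening: models, matching and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ph4screen)
```

## The problem

Multi-kinase inhibitors that bind the inactive (DFG-out) conformation of
several kinases at once — for instance VEGFR-2, FGFR-1 and BRAF, three
targets on the angiogenic signalling axis — share a recognisable
interaction signature: a hydrogen-bond acceptor toward the hinge-region
cysteine/alanine backbone, a donor toward the conserved alpha-C-helix
glutamate, an acceptor toward the DFG-motif aspartate, and a bulky
hydrophobic group filling the allosteric back pocket. A *pharmacophore*
abstracts this signature into typed tolerance spheres in 3D space; a
molecule "matches" when one of its conformers can present a compatible
feature at each required sphere, and excluded volumes reject poses that
would penetrate receptor-occupied space.

`ph4screen` implements the full computational route around such models:

1. **building** candidate models from superposed protein–ligand
   complexes (`align_complexes()`, `detect_interactions()`,
   `cluster_common_features()`, `place_excluded_volumes()`,
   `enumerate_hypotheses()`);
2. **screening** conformer libraries against a model
   (`perceive_features()`, `distance_prefilter()`,
   `kabsch_superpose()`, `match_conformer()`, `screen_library()`);
3. **validating** models on labelled active/decoy test sets with an
   eight-metric suite and ranking (`confusion_from_screen()`,
   `compute_metrics()`, `rank_models()`, `back_solve_counts()`);
4. **simulating** every input the pipeline needs
   (`plant_matched_library()`, `make_toy_complex()`), so the whole chain
   is testable without downloads.

## Feature perception

Perception works on the molecular graph of each conformer (explicit
hydrogens required wherever a donor is expected):

* **donors** — N or O bearing at least one explicit hydrogen;
* **acceptors** — N or O, not positively charged, amide nitrogens
  excluded;
* **hydrophobes** — carbon rings of ≥ 5 atoms and acyclic all-carbon
  chains of ≥ 3 atoms, each reduced to its unweighted centroid.

These are conventional pharmacophore typing rules; commercial packages
each use their own unpublished variants, so agreement with any particular
vendor's screen is neither expected nor claimed. Output order is fixed
(kind, then lowest owning atom index), which pins every downstream
tie-break and makes runs bit-reproducible.

Projected site points encode hydrogen-bond directionality. A donor's
projection lies `projection_distance` (default 3.0 Å, a typical
donor–acceptor distance) along the heavy-atom→H unit vector; when a donor
carries several hydrogens the lowest-indexed one is used, a deterministic
choice that matters only for symmetric donors such as ammonium. An
acceptor's projection points opposite the mean unit vector to its bonded
heavy neighbours (the lone-pair direction); if an acceptor has only
hydrogen neighbours those are used instead, and a degenerate (near-zero)
mean direction suppresses the projection rather than inventing one.

## Matching and screening

Matching a conformer against a query has three stages.

**Prefilter.** All injective, kind-compatible assignments of molecule
features to the query's required features are enumerated, pruned by
pairwise distance distortion: a pair (i, j) may deviate by at most
`slack_ij`. The base slack is `radius_i + radius_j` — admissible for
tolerance-sphere matching by the triangle inequality. When a hit
threshold `T` is known the slack is widened to
`max(radius_i + radius_j, sqrt(2m)·T)` over the `m` required features.
The widened rule is provably lossless with respect to the threshold: a
mapping whose optimal-superposition RMSD is `r` has per-feature
deviations `d_k` with `sum(d_k^2) = m·r^2`, so any pair satisfies
`|Δd_ij| ≤ d_i + d_j ≤ sqrt(2(d_i^2 + d_j^2)) ≤ sqrt(2m)·r`; a pruned
mapping therefore has `r > T`.

**Rigid superposition.** Each surviving mapping is scored by the
least-squares proper rotation (Kabsch algorithm, via SVD of the
cross-covariance of the centred point sets) of the mapped molecule
feature centers onto the query centers. Reflections are disallowed; for
degenerate input with no spatial extent the identity rotation and
centroid translation are returned. RMSD is computed over feature centers
(main and projected), not atoms — the fitness criterion is deviation
from the query feature points. The minimum-RMSD mapping wins, ties
resolved by lexicographic enumeration order. If no surviving mapping
beats the threshold, the search re-runs without distance pruning, so the
reported RMSD is always the exact global minimum over all injective
kind-compatible mappings (verified against an exhaustive permutation
oracle in the test suite).

**Excluded volumes.** The winning transform is applied to all conformer
atoms; a clash occurs iff an atom center is strictly closer than
`volume_radius + atom_radius` to a volume center (an atom exactly on the
boundary does not clash — a documented tie rule). `atom_radius` defaults
to 1.0 Å, a generic heavy-atom radius.

A conformer is a **hit** iff a mapping exists, its RMSD is at most
`rmsd_threshold`, and no volume clashes. The default threshold is 1.0 Å
over matched feature centroids: screens of this kind report winning hits
just under that value (e.g. a best hit at 0.979 Å), and the exact cutoff
used by commercial engines is unpublished, so 1.0 Å is adopted as the
package default and is configurable everywhere. By default *all* query
features are required (no partial matching); `required_feature_ids`
supports partial matching when wanted. A molecule is a hit iff at least
one of its conformers is; its reported RMSD is the minimum over
conformers, ties to the lowest conformer index.

## Building models from complexes

Complexes are superposed on paired alpha carbons with the same Kabsch
machinery (at least 3 pairs, collinear sets rejected), so co-crystallised
ligands land in one frame. Interactions are then detected with
field-conventional cutoffs, none of which are prescribed by published
screens and all of which are configurable:

| parameter | default | meaning |
|---|---|---|
| `hbond_max_da` | 3.5 Å | donor–acceptor heavy-atom distance |
| `hbond_min_angle` | 120° | D–H···A angle at the hydrogen |
| `hydrophobic_max_dist` | 4.5 Å | centroid-to-apolar-atom distance |
| `hydrophobic_min_group` | 3 | apolar protein atoms within range |
| cluster `tolerance` | 1.5 Å | single-linkage link distance |
| `min_support` | all complexes | features must be common |
| volume `shell` / `keepout` | 5.0 / 2.0 Å | candidate shell, feature clearance |
| `volume_radius` / `max_count` | 1.0 Å / 30 | placed volumes |

Ligand-side donors need explicit hydrogens; for ligand *acceptors* the
protein partner must itself donate, which requires an explicit polar
hydrogen on the protein N/O (attached by a 1.3 Å distance rule, since
PDB files carry no connectivity). Structures without modelled hydrogens
therefore yield no ligand-acceptor hydrogen bonds — a deliberate
precision-over-recall choice that keeps the angle criterion honest.

Like-kind interaction points from all complexes are clustered by
single-linkage (`stats::hclust`); clusters supported by enough distinct
complexes become features at their centroid. Excluded-volume placement
is greedy maximin over binding-site protein heavy atoms with canonical
tie-breaks, so volume sets are deterministic. Hypothesis enumeration is
specification-driven (named feature subsets with optional radius
overrides), not combinatorial: published model series of this kind (17
hand-built combinations in the motivating study) are curated by hand and
unlisted, so the package reproduces the *mechanism*, with the
illustrative `example_multikinase_model()` standing in for the
unpublished geometry (its JSON copy ships as
`extdata/multikinase_ph4_synthetic.json`, clearly labelled synthetic).

## Validation metrics

For a labelled screen with `tp`, `fp`, `tn`, `fn` and totals
`A = tp + fn` actives, `D = tn + fp` decoys, `N = A + D`:

* sensitivity `se = tp/A`, specificity `sp = tn/D`;
* yield of actives (precision) `ya = tp/(tp+fp)`;
* enrichment `e = ya · N/A` — the hit list's active rate over the
  whole-set prevalence, pinned to total-set prevalence by the worked
  benchmark value (`ya = 0.377`, `N/A = 2387/73` gives `e = 12.318`);
* accuracy `acc = (tp+tn)/N`;
* discrimination ratio `dr = se/sp`. No formula for this quantity is
  printed with the benchmark table; `se/sp` is the only simple ratio
  that reproduces every one of its 17 rows (e.g. 0.753/0.961 → 0.784,
  0.849/0.773 → 1.099, 0.425/0.986 → 0.431) and is adopted as derived;
* `f1 = 2tp/(2tp+fp+fn)`, the harmonic mean of `se` and `ya`, flagged
  undefined whenever `ya` is;
* Matthews correlation
  `mcc = (tp·tn − fp·fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.

Metrics with a zero denominator are flagged undefined, never silently
zero. Raw values are exact double ratios; reporting applies half-up
rounding at table precision (3 decimals, except 4 for `f1` and `mcc`),
matching how such tables are printed. Aggregation across targets sums
the integer counts first — metrics of sums, never averages of metrics.

`back_solve_counts()` inverts rounded `se`/`ya` back to integer counts
by exhaustive search, and `consistent_counts()` checks a full printed
row for an integer-consistent confusion matrix; the bundled 17-row
benchmark table passes this check row by row in the test suite, which is
also what fixes the `dr` formula above.

```{r metrics-example}
m <- compute_metrics(confusion_counts(tp = 55, fp = 91, tn = 2223, fn = 18))
round_metrics(m)
back_solve_counts(0.425, 0.484, A = 73, D = 2314)
```

## What the synthetic generator emulates — and what it does not

`plant_matched_library()` reproduces the *structure* of a published
three-kinase validation experiment: per-target test sets of 26/801,
20/600 and 27/913 actives/decoys (2387 compounds, decoy:active ≈ 30,
mimicking the active rate of real screening space), with a prescribed
number of geometric matches planted per target. Planted matchers carry
minimal chemically valid fragments — a formaldehyde oxygen (acceptor),
an ammonium nitrogen (donor-only, being cationic), a propane centroid
(hydrophobe) — at the query feature positions plus a bounded jitter,
under a random rigid motion, so the library genuinely exercises
perception, prefiltering and superposition. Non-matchers lack one
required feature kind (or have all pairwise distances doubled), so their
rejection is analytic, not probabilistic, and the planted confusion
matrix is recovered *exactly*. Generators are pure functions of their
seeds; the SDF and CSV they write are byte-stable.

What passing these tests does **not** show: real decoys are
property-matched but topologically diverse molecules whose features
*almost* fit — the generator's non-matchers fail categorically, so the
planted recovery says nothing about borderline discrimination. Nor do
single-conformer fragment "molecules" probe conformational flexibility,
tautomerism or protonation; conformer generation is explicitly the
library's job. Reproducing a published screen's exact hit RMSDs would
require the original conformer ensembles and model geometry, neither of
which is public.

## Numerical and design choices

* Coordinates are right-handed Cartesian ångströms throughout; no
  periodicity.
* Model JSON uses a canonical writer (fixed key order, 6-decimal
  floats): two saves of one model are byte-identical, and save→load is
  the identity at that resolution. Feature radii absent from input
  default to 1.0 Å (main) / 1.5 Å (projected), typical pharmacophore
  tolerances.
* The package's own V2000 SDF layer preserves `M  CHG` formal charges
  (which the acceptor rule needs) and writes byte-stably; an independent
  parser cross-checks it in the tests.
* All tie-breaks (feature ordering, mapping enumeration, conformer
  selection, maximin volume placement, ranking) are lexicographic and
  documented, so identical inputs give identical outputs.
* Degenerate inputs have defined behaviour: coincident point sets fall
  back to the identity rotation; fewer than 3 alignment pairs, collinear
  alpha-carbon sets, empty test sets and unscreened labelled compounds
  raise classed errors.
* Test-suite problem sizes: the full 2387-compound planted benchmark
  runs once end to end; matcher-versus-oracle properties use 1000
  random instances with ≤ 5 query features; planted-recovery designs use
  20 random libraries of 25–144 compounds. These sizes give exact
  combinatorial coverage where exactness is claimed and keep the default
  suite fast.

## Known limitations

* Feature typing is rule-based on explicit graphs: no aromaticity
  perception beyond carbon rings, no charged-center or ring-normal
  feature kinds, no tautomer or protonation enumeration.
* PDB ligand bonds are inferred from covalent radii; unusual geometries
  may gain or lose bonds, and formal charges are not recoverable from
  PDB input.
* Hypothesis enumeration is curated, not automatic: the package will not
  invent feature combinations.
* The screening engine is rigid: conformational sampling must be done
  upstream, and scoring is geometric RMSD only (no energies).
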