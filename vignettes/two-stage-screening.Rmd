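---
title: "Two-stage virtual screening: stacked hit identification and interaction-count rescoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage virtual screening: stacked hit identification and interaction-count rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitstack)
```

## The screening problem

Ligand-based virtual screening ranks candidate molecules by how much
their computed features resemble those of known actives;
structure-based screening ranks them by how well they interact with the
target's binding pocket. `hitstack` chains the two: a **chemical-space
(CS)** classifier trained on molecular descriptors proposes hits, and a
**protein-space (PS)** classifier trained on substructure-count
fingerprints of docked complexes — fused with a per-complex interaction
count — re-ranks them into an optimized short list.

Labels come from measured potency: a molecule is an inhibitor
(class 1) when its IC50 is strictly below a cutoff, 0.05 µM by default
(`label_by_potency()`).

## Descriptor preprocessing

Raw descriptor tables contain uninformative and redundant columns.
`preprocess_descriptors()` applies three filters in a fixed order:

1. **Sparsity** — drop columns whose fraction of exact zeros is
   *strictly greater than* 0.85. Values are not rounded first, so a
   descriptor taking tiny nonzero values is not mistaken for sparse.
2. **Low variability** — drop columns with sample standard deviation
   (n−1 denominator) *strictly below* 0.03. The 3% rule is read as an
   absolute threshold on the raw descriptor scale, because the input
   is not normalized at this stage; a coefficient-of-variation reading
   (`relative = TRUE`) is offered since either convention is found in
   preprocessing practice.
3. **Correlation** — drop the *later* column of any pair with absolute
   Pearson correlation strictly above 0.90, scanning left to right so a
   removed column can never cause further removals. Keeping the earlier
   column is the common deterministic convention; absolute correlation
   is used because an anti-correlated duplicate is just as redundant.

The fixed order matters: constant columns must be gone before
correlations are computed (correlation is undefined at zero variance,
and `filter_correlated()` refuses to guess). The chain is idempotent —
a second application removes nothing — which the tests assert over many
seeds.

## The chemical-space stacked ensemble

Given the filtered training set \(\mathcal{D} = \{(x_n, y_n)\}_{n=1}^N\),
`cs_stack()` builds a two-tier model:

* **Tier 0.** \(T\) base learners (random forest and extreme gradient
  boosting by default) are trained under \(J\)-fold cross-validation
  (J = 10 by default). The out-of-fold prediction
  \(z_{nt} = h_t^{(-j)}(x_n)\) is produced by the model that never saw
  instance \(n\)'s fold.
* **Tier 1.** The level-one set
  \(\{(z_{n1},\dots,z_{nT}), y_n\}\) trains the super learner \(H\), a
  feed-forward network with hidden layers (200, 400), Tanh activations,
  a 2-unit softmax output and 50 training epochs. For deployment the
  base learners are refitted on the full data; a new molecule flows
  through the refitted bases into \(H\).

Out-of-fold stacking is what keeps the super learner honest: tier-1
inputs for instance \(n\) carry no information about \(y_n\) beyond what
a genuinely held-out model could extract. The test suite verifies this
with a *memorizing* base learner (1-nearest-neighbour on training rows):
on label-shuffled data its out-of-fold AUC stays at chance across 20
seeds, whereas scoring its own training rows would give AUC ≈ 1.

Base-learner outputs are passed to the super learner as positive-class
*probabilities*, not hard labels — a weighted combination of graded
inputs is what gives stacking its resolution. The output layer is a
softmax rather than Tanh because class probabilities summing to one are
required downstream; Tanh is used on the hidden layers only.

### Evaluation metrics

`classification_metrics()` reports accuracy, sensitivity Se,
specificity Sp, rank-based (Mann–Whitney, mid-rank ties) AUC, and the
balanced classification rate

\[\mathrm{BCR} = \frac{S_e + S_p}{2}\,(1 - |S_e - S_p|),\]

which collapses to balanced accuracy when Se = Sp and penalizes
imbalance otherwise. Ensemble diversity is measured by the non-pairwise
entropy

\[E = \frac{1}{N} \sum_{i=1}^{N}
    \frac{\min(\theta_i,\, T - \theta_i)}{T - \lceil T/2 \rceil},\]

where \(\theta_i\) is the number of classifiers misclassifying
instance \(i\). This is the standard disagreement-based diversity
measure bounded in [0, 1]: 0 when all classifiers behave identically,
1 when every instance splits the ensemble as evenly as possible. (A
product reading \(\min\{\theta_i(T-\theta_i)\}\) of the same expression
is not bounded by 1 and is therefore not what the 0–1 range implies;
the ratio form is implemented.)

## The protein-space module

Docked complexes are summarized two ways.

**Fingerprints.** `compute_fingerprint()` counts, for each of 4860
substructure queries, the unique matches in the ligand (binary mode is
the indicator `count > 0`). Substructure counting applies to the
ligand, not the protein — a substructure query has no meaning on a
receptor — so the ligand of each complex is what gets fingerprinted.
The package ships a **synthetic** pattern library
(`inst/extdata/synthetic_substructure_library.smarts`): the canonical
4860-pattern Klekota–Roth list cannot be redistributed here, so a
deterministic enumeration of 4860 distinct valid SMARTS (element chains
of length 1–4 over eight elements, plus substituted ring cores) stands
in with identical cardinality, ordering guarantees and count semantics.
`build_substructure_library()` regenerates it bit-for-bit, and
`load_library()` verifies the packaged file against that enumeration at
every load. Match counting uses unique-match semantics
(symmetry-equivalent mappings collapsed), configurable because both
conventions exist among fingerprint engines.

**Interaction profiles.** `interaction_profile()` types protein–ligand
contacts with simplified geometric rules whose default cutoffs follow
published interaction-profiling conventions: hydrogen bond
donor–acceptor heavy-atom distance ≤ 4.1 Å (donor angle ≥ 100° when an
explicit hydrogen is present); apolar carbon–carbon contact ≤ 4.0 Å;
salt-bridge charged-group centroid distance ≤ 5.5 Å; π-stacking
ring-centroid distance ≤ 5.5 Å with interplanar angle ≤ 30° (parallel)
or ≥ 60° (T-shaped); π-cation centroid–cation distance ≤ 6.0 Å. All
cutoffs live in `interaction_rules()`. Hydrogens are optional: absent
hydrogens, donors are inferred from heavy-atom residue templates.
Charge assignment uses residue templates (Asp/Glu acidic, Lys/Arg/His
basic) and ligand formal charges from the PDB file; there is no pKa
model. Two de-duplication rules keep one physical contact to one
record: a contact between oppositely charged groups is a salt bridge
only (never also a hydrogen bond), and apolar contacts between the two
rings of a detected π-stack are suppressed. Each record is unique per
(type, residue, ligand atom-or-ring), and `d_i` is the record count.
Alternatively `ingest_plip_report()` accepts an external profiler's XML
or text report and counts with the same semantics; water bridges,
halogen bonds and metal complexes map to an `"other"` type that is
included in `d_i` by default (a toggle exists, since which categories a
pocket-profile window was calibrated against can vary).

**The optimization score.** The PS classifier `ps_net()` is a
(400, 200, 400, 2) network — Tanh on the first three layers, softmax
output, 50 epochs — trained on the count matrix under fivefold
cross-validation with a grid search over momentum, rate annealing and
input-dropout ratio. The grid point with the highest mean CV AUC wins
(ties: higher mean accuracy, then grid order — a criterion had to be
fixed and mean CV AUC is the natural one for a ranking model); the
final network is refitted on all data at that point. For a candidate
with positive-class output \(f(\alpha)\) and interaction count
\(d_i\), the optimization score is

\[\beta = f(\alpha) + d_i.\]

\(f(\alpha)\) is the *probability*, not the hard label: with a hard
label every window-passing candidate would score \(1 + d_i\) and the
re-ranking would collapse to the integer count. Because
\(f(\alpha) < 1\), β orders candidates primarily by \(d_i\) and breaks
ties within a count by classifier confidence.

**Windowed ranking.** `rank_hits()` keeps candidates whose \(d_i\)
falls in an inclusive target-specific window — e.g. [9, 12] for a
CXCR4-like pocket, [6, 8] for an androgen-receptor-like pocket — and
sorts them by β descending (ties: higher \(f(\alpha)\), then id).
With labels supplied it ranks only true positives (the evaluation
convention); in deployment it ranks all predicted positives, and the
mode is recorded in the output's attributes.

## The neural-network engine

No multi-hidden-layer network implementation is part of the package's
dependency set, so `mlp()` implements one directly: Tanh hidden layers,
2-way softmax output, cross-entropy loss, mini-batch SGD with classical
momentum, learning-rate annealing \(\eta_t = \eta_0 / (1 + \lambda t)\)
and inverted input dropout. Weights start from a uniform
fan-in/fan-out-scaled range; all randomness (initialization, batch
order, dropout) flows from one integer seed, so fits are exactly
reproducible. Inputs are standardized by default, but `ps_net()`
disables this for count data: background fingerprint columns are
near-constant (mostly zeros), and standardizing them turns a rare count
of 1 into a several-sigma spike that dominates the first-layer
activations — raw counts are already on a homogeneous scale, and
leaving them raw lets the L2 penalty suppress the noise columns
naturally. Ties at the 0.5 probability cut are called positive
everywhere, so a boundary case can never silently disappear between
stages.

## What the synthetic generators emulate

* `gen_descriptor_matrix()` — a two-class descriptor table with planted
  sparse (≥ 90% zeros), constant and duplicated columns whose removal
  set is known exactly, and informative columns whose class means
  differ by `class_sep` (default 1.5; 2 in the packaged study, a
  cleanly separable but not trivial regime).
* `gen_fingerprint_dataset()` — a sparse Poisson count matrix of
  library width (background rate 0.05) with `k_informative` columns
  whose rate rises by `effect` in the positive class. `effect = 0` is
  an exact null.
* `gen_complex()` — a toy PDB whose residues and LIG group satisfy
  exactly one geometric rule per planted contact. Slots are 30 Å
  apart and decoy atoms sit far outside every cutoff. Planted
  geometries keep the largest feasible margin from all *other* rules'
  cutoffs; for a salt bridge the hydrogen-bond cutoff (4.1 Å) and the
  salt-bridge cutoff (5.5 Å) leave only a 1.4 Å corridor, so there the
  margin is ~1 Å and the charged-pair routing rule, not distance alone,
  is what guarantees single-firing.
* `gen_activity_table()` — a potency-annotated molecule table whose
  class composition at the cutoff is exact by construction (IC50 values
  are drawn log-uniformly strictly on each side of it).
* `gen_screening_study()` — the packaged end-to-end study: shared
  labels across both feature spaces, with interaction counts inside the
  window for every active and outside it for every inactive.

What these do **not** emulate: real descriptor distributions are
heavy-tailed and block-correlated, real fingerprints are correlated
through shared substructures, real docked poses produce noisy,
target-dependent contact counts, and real activity cliffs put near-identical
molecules on opposite sides of the potency cutoff. A pipeline that
passes the synthetic suite is internally correct — filters remove what
they claim, stacking leaks nothing, geometry fires the right rule,
ranking follows β — but its headline numbers say nothing about
performance on a particular receptor's chemistry.

## Numerical choices and degenerate inputs

* Strict inequalities at every filter boundary (a column *at* a
  threshold survives), matching the "more than" / "less than" wording
  of the rules.
* Fold assignment: sizes differ by at most one; stratified assignment
  deals each class round-robin from a random offset, keeping per-fold
  class counts within one of each other (fold *totals* may then differ
  by up to the number of classes). A class smaller than J is an error.
* AUC is undefined for single-class truth and reported as `NA` with a
  warning; the remaining metrics are still computed.
* `rank_hits()` with an unbounded window reduces exactly to a β sort,
  which the tests check against an independent ordering oracle.
* Problem sizes in the packaged study and tests — n = 300 descriptor
  instances, n = 200/100 train/eval in the end-to-end study, fivefold
  PS CV with a single default grid point, reduced network widths in
  property tests that do not exercise the full architecture — were
  chosen as the smallest sizes at which the studied effects are stable
  across seeds.

## Known limitations

* The interaction profiler is deliberately simplified: no water-mediated
  bridges, no halogen-bond sigma-hole geometry, no pKa-dependent
  protonation, top pose only (first MODEL of a multi-model file). For
  fidelity to a published profiler, ingest its report instead.
* The substructure library is a synthetic stand-in with the canonical
  cardinality, not the Klekota–Roth pattern set itself; fingerprints
  are comparable within this package but not across tools.
* `ps_net()` on the full 4860-wide architecture costs tens of seconds
  per fit on one core; grid size multiplies that by `folds + 1` fits
  per point.
* Binary classification only; the window bounds are a configuration
  value whose calibration (from a pocket's pharmacophore profile) is
  outside the package's scope.
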