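---
title: "Benchmarking molecular property prediction: methodology and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking molecular property prediction: methodology and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

qsareval implements an evaluation methodology for molecular property
prediction (QSAR) models: not the models themselves, but everything around
them that determines whether a reported improvement is real — data curation,
featurization, splitting, metric choice, statistical comparison, and the
structure-aware failure modes (activity cliffs, near-cutoff edge cases) that
aggregate metrics hide. This vignette explains the procedures, their
assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## The data model

Activity records arrive as SMILES plus a potency in nM (IC50, EC50, Ki or Kd
pooled by default; a `measure` argument restricts to one). Potencies are
converted to pIC50 = 9 − log10(value in nM), the negative decadic logarithm
of the molar concentration, so 1 µM maps to pIC50 6 — the conventional
active/inactive cutoff. Only records with relation "=" are accepted;
censored values (">", "<") are rejected at load time because they are not
point measurements.

Curation (`curate()`) canonicalizes SMILES through RDKit, removes molecules
whose raw SMILES exceeds 400 characters (the cap used when sequence models
with fixed padding share the data), collapses exact duplicates, and handles
repeated measurements of one molecule by a rule the source protocols leave
open: if the values span more than `contradiction_span` (default 1.0 log
unit, roughly inter-assay reproducibility), the molecule is contradictory
and dropped; otherwise the median is kept. The median is robust to a single
outlying assay and reduces to the mean for pairs; the span rule is exposed
as a parameter because there is no field consensus. Curation sorts before
aggregating, so its output is independent of input row order.

Classification datasets derive from regression ones via `binarize()`:
active iff pIC50 ≥ cutoff (default 6), matching the convention that values
below the cutoff are inactive.

## Representations

Six fixed representations are computed through RDKit behind one interface
(`compute_representation()`):

* **PhysChem** — exactly 11 drug-likeness descriptors in a pinned order
  (MolWt, MolLogP, NumHDonors, NumHAcceptors, NumRotatableBonds, NumAtoms,
  NumHeavyAtoms, MolMR, PSA, FormalCharge, NumRings). NumAtoms counts
  implicit hydrogens; NumHeavyAtoms does not — the two must differ for the
  pair to be informative.
* **RDKit2D** — the toolkit's full 2D descriptor list (~200 columns). The
  dimensionality is recorded at run time rather than hard-coded because it
  is toolkit-version dependent. An optional rank-based normalization to
  (0, 1) is off by default; the exact normalization used by pretrained
  pipelines varies, so it is left pluggable.
* **MACCS** — 166 structural keys (the toolkit's unused key 0 is dropped,
  pinned for cross-version stability).
* **MorganBits / MorganCounts** — circular (ECFP-style) fingerprints,
  radius 2, 2048 bits by default; counts retain substructure multiplicity.
* **AtomPairs** — hashed atom-pair fingerprint, 2048 bits.

Descriptor failures on single molecules are imputed with the column median
of the successful rows and the affected ids recorded — matrices stay
rectangular without silently dropping molecules. Tanimoto similarity is
defined on bit vectors as |A∧B|/|A∨B| with the convention that two all-zero
fingerprints are identical (similarity 1), which avoids an arbitrary 0/0.

## Splitting

Both split families produce 80:10:10 train/validation/test partitions and
are repeated over seeds 0..29 by default (`split_protocol()`); every
downstream experiment reuses the same persisted manifests.

`random_split()` permutes ids with a seeded generator and cuts by floor
arithmetic. `scaffold_split()` is the balanced Bemis–Murcko variant used by
message-passing benchmark pipelines: molecules are grouped by scaffold
(acyclic molecules form the single empty-scaffold group), groups larger than
half the test target are queued first (largest first, ties broken by the
scaffold string), the rest are shuffled with the seed, and groups fill
train, then validation, then test. No scaffold ever crosses a partition.
Scaffolds are achiral Murcko frameworks; chirality flags are not part of
the grouping key. Each split draws from its own explicitly seeded generator
— no global random state is consumed or disturbed.

## Metrics

Classification: AUROC via the rank (Mann–Whitney) formulation with
half-credit for ties; AUPRC as step-wise average precision (no trapezoidal
interpolation, which is optimistic on sparse curves); PPV = TP/(TP+FP) and
NPV = TN/(TN+FN) at a fixed operating point. The threshold policy: an
explicit threshold wins; otherwise Youden's J threshold is used when the
minority class is below 40%, else 0.5. `youden_threshold()` maximizes
TPR − FPR over the distinct score values (a score ≥ threshold is called
positive), compares candidate cut points with exact integer arithmetic so
mathematically tied J values are recognized as ties, and resolves ties
toward the higher threshold — the conservative operating point. The
threshold is fit on the same prediction set being evaluated, which is an
optimistic convention; callers wanting a held-out threshold can pass one
explicitly. Zero-denominator PPV/NPV are reported as NA, never as 0, so
aggregation cannot silently absorb undefined values.

Regression: RMSE, MAE, R² against the label-mean baseline (can be
negative), and Pearson r (NA for constant inputs). R² ≤ r² always holds —
r² is the best R² attainable by affinely rescaling the predictions — which
is why the two must not be conflated when comparing models.

## Statistical comparison

Per-seed metric vectors are compared with a two-sided Mann–Whitney U test
(`mann_whitney_u()`): exact null enumeration (a dynamic-programming count of
the U distribution) when the combined sample is ≤ 16 without ties, otherwise
the normal approximation with tie and continuity corrections. α = 0.05, no
multiple-testing correction by default (a `p.adjust` method can be enabled)
— mirroring the practice of reporting unadjusted pairwise p-values alongside
means ± standard deviations over 30 seeds.

`count_wins()` quantifies how misleading mean-only comparisons can be:
single mode counts, per seed, which model is best; triple mode enumerates
all C(30, 3) = 4060 three-seed combinations and counts which model has the
best mean in each — emulating the common "average over 3 splits" practice.
Exact ties (relative tolerance 1e-12) award no model and are counted
separately. `impute_nonsignificant()` zeroes differences whose p-value
exceeds α before plotting method-vs-method gaps, and
`variability_analysis()` correlates per-model metric means with their
standard deviations across seeds.

## Activity cliffs and edge cases

A scaffold is an activity-cliff (AC) scaffold when its members' pIC50 span
at least 2 log units (inclusive, "at least two orders of magnitude");
molecules bearing such scaffolds are AC molecules. The annotation is
computed on the full curated dataset — it is a dataset property, like a
summary table — and per-split AC fractions are derived from manifests.
A 1-log-unit criterion can be set via `span_threshold`.

Edge cases are molecules in scaffold groups that straddle the
classification cutoff inside the pIC50 window [5, 7]: the group must have a
member in [5, 6) and one in [6, 7], and members inside the window are
flagged. The straddle reading was chosen (over "group span reaches from 5
to 7") because edge cases are motivated as analogs coerced into opposite
classes by the cutoff; a group entirely on one side is not coerced.
`stratify_predictions()` splits any prediction set into all/AC/non-AC and
edge-removed views so every metric can be reported per stratum.

## The synthetic generator

The generator exists so that every stage above is testable against planted
ground truth without any external downloads. It emulates the shape of
target-binding datasets, not their pharmacology.

Molecules are assembled by substituting small acyclic fragments (methyl,
ethyl, propyl, chloro, fluoro, hydroxyl, amino, acetyl, aldehyde, methoxy)
onto ring-scaffold SMILES templates: 7 core rings × 20 second-ring
fragments × 8 linkers, giving 952 distinct Murcko scaffolds and ~93,000
enumerable molecules. Assembly is template substitution on SMILES strings
with validity re-checking through RDKit — simpler and more reproducible
than graph editing, with enough diversity for testing. Every emitted SMILES
parses, is stored canonicalized, and carries a non-empty scaffold shared by
its whole group; the substitution patterns keep the attachment atom's ring
environment fixed across arities so a group's members genuinely share one
scaffold.

Labels follow an additive model: scaffold base + substituent effects
(bounded so non-cliff groups span < 1.4 log units) + planted terms + noise.
Scaffold bases are skew-normal (default location 4.5, scale 1.2, shape 3 —
right-skewed, as screening data mostly contains weak binders), then shifted
by a deterministic calibration so the positive rate at cutoff 6 hits a
target (default 0.30, the order of the µ-opioid receptor dataset's 29.7%).
Activity cliffs are planted in 10% of scaffolds by default: one designated
member's noiseless label is set to the group maximum plus `cliff_magnitude`
(default 2.5), which guarantees the planted span by construction; AC groups
are drawn larger (18–30 members) than ordinary groups (2–6) so that ~10% of
scaffolds carry ~40% of molecules, the burden observed in opioid-target
data. Edge groups (default 10% of scaffolds) have their base pinned to the
cutoff and members squashed to within ±0.45 log units of it, straddling it
on both sides: close enough that assay-scale Gaussian noise (σ ≈ 0.4)
flips binarized classes, which is the defining fragility of edge cases. An
earlier ±0.9 placement left most planted "edge" molecules two noise
standard deviations from the cutoff — not fragile at all — and was revised
accordingly. All planted structure (bases, effective per-molecule effects,
AC and edge flags, noiseless labels) is recorded, and noiseless labels
reproduce exactly as base + effect.

Noise models: none (default), i.i.d. Gaussian, or heteroscedastic with
standard deviation σ₀ + k·|y − y₀| — potency measurement error growing away
from a reference point. Clean labels are retained alongside.

Descriptor datasets (`generate_descriptor_dataset()`) sample from the full
template library and label each molecule with MolWt or NumAtoms computed
from its own structure, so labels are exactly recomputable; the size ladder
is pinned to 16 sizes from 0.1K to 100K (0.1, 0.2, 0.4, 0.6, 0.8, 1, 2, 4,
6, 8, 10, 20, 40, 60, 80, 100 ×1000 — a reconstruction: published lists of
these ladders elide the middle values). Requests beyond the ~93K enumerable
library are errors rather than silent sampling with replacement.

What the generator does *not* emulate: real pharmacology (substituent
effects are additive and context-free, real SAR is not), stereochemistry,
measure-type heterogeneity, and the long tail of rare scaffolds in screened
libraries. Tests passing on synthetic data therefore validate the
*methodology* — splitting, annotation, metrics, statistics — not any claim
about prediction accuracy on real targets.

## Models

Baselines are deliberately standard: random forest (500 trees, the
conventional strong baseline configuration), linear-kernel SVM, and
gradient-boosted trees (100 rounds, learning rate 0.3, depth 6). They fit
on the training partition only; the validation partition is carried in
every manifest for plug-in models that need it (e.g. neural nets with
early stopping) but is unused by the traditional baselines. Classification
scores are probabilities where the model provides them (RF, XGBoost) and
min-max-scaled decision values for the SVM; the convention is recorded in
provenance. An `external` model type wraps prediction tables produced
outside the package so the metric and statistics layers can compare, say, a
pretrained transformer against these baselines without training it here.
The random forest is fit with ranger, single-threaded and seeded, so the
whole pipeline is reproducible at the prediction level given the manifest
and model seeds.

`run_benchmark()` orchestrates curate → split → featurize → train →
evaluate (including AC-stratified views) with every intermediate persisted;
cells are content-addressed by their provenance hash, reruns skip completed
cells, and failures are recorded per cell without stopping independent
work. `sweep_cutoffs()` re-binarizes at each cutoff in a list, records
per-cutoff metrics and positive rates, collects the predicted probabilities
of edge-case molecules, and records cutoffs that yield single-class
training sets as skipped cells.

## Numerical choices and problem sizes

* Youden and win-counting ties are resolved with exact integer arithmetic
  and a relative 1e-12 guard, respectively; float round-off must not decide
  winners.
* The Mann–Whitney exact/approximate switch at combined n = 16 keeps the
  exact path cheap (the DP is O(n₁n₂·(n₁+n₂))); at 15 + 15 the two paths
  agree within 0.02 in p.
* Undefined quantities (zero-variance correlations, zero-denominator
  predictive values, constant-input Pearson r) are NA throughout and
  serialize as JSON nulls.
* Test and acceptance runs use scaled-down problem sizes chosen for
  statistical adequacy rather than completeness: the opioid-like condition
  is 100 scaffolds (~600 molecules), the split-invariant sweeps use 5
  datasets × 30 seeds, the descriptor ladder is exercised at 100/1,000/
  10,000 molecules over 3 seeds, and the edge-case study uses 200 scaffolds
  (~1,400 molecules) over 10 seeds — large enough that the test partition
  (~140 molecules) gives stable AUROC medians.

## Known limitations

* The canonical-SMILES identity used for deduplication ignores
  stereochemistry: enantiomers with distinct labels collapse or conflict.
* The Youden threshold is fit on the evaluated predictions (optimistic);
  pass an explicit threshold for honest operating-point metrics.
* The scaffold split is one pinned balanced variant; other implementations
  order or assign groups differently, and absolute metric values are not
  comparable across variants.
* Heteroscedastic noise is symmetric Gaussian around the clean label;
  censoring (">" records) is rejected, not modeled.
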