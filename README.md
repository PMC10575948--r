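# qsareval

Rigorous evaluation methodology for molecular property prediction (QSAR)
models, as an R package.

Most reported "improvements" in molecular property prediction rest on a
fragile evaluation stack: ad-hoc data splits, mean metrics over a handful of
seeds without statistical tests, metrics that hide what practitioners care
about (a high AUROC can coexist with a useless positive predictive value),
and no accounting for activity cliffs — analog series in which a minor
structural change swings potency by orders of magnitude. qsareval implements
that evaluation stack properly, end to end, for anyone benchmarking QSAR
models on activity data (medicinal chemists, cheminformaticians, ML
researchers):

* **Curation** — SMILES canonicalization (RDKit), pIC50 = 9 − log10(nM)
  conversion, relation filtering, duplicate collapse, contradiction removal,
  400-character length cap, with a per-rule removal log.
* **Representations** — the 11 PhysChem descriptors, RDKit2D, 166-key MACCS,
  Morgan bit/count fingerprints (radius 2, 2048 bits), atom-pair
  fingerprints; Tanimoto similarity.
* **Splitting** — seeded random and balanced Bemis–Murcko scaffold splits at
  80:10:10, repeated over seeds 0..29, persisted as JSON manifests reused by
  every experiment.
* **Cliff & edge annotation** — AC scaffolds (pIC50 span ≥ 2 log units
  within a scaffold), AC molecules, near-cutoff edge cases (groups
  straddling the cutoff inside pIC50 5–7), and AC-stratified evaluation.
* **Metrics** — AUROC (rank formulation), AUPRC (average precision),
  PPV/NPV at Youden-J thresholds, RMSE, MAE, R², Pearson r, with exact
  tie handling and NA (never 0) for undefined values.
* **Statistics** — two-sided Mann–Whitney U (exact enumeration for small
  samples, tie/continuity-corrected normal otherwise, α = 0.05), pairwise
  model comparison, single-fold and triple-split win counting,
  non-significant-difference imputation, variability and residual analysis.
* **Models** — RF (500 trees), linear SVM, XGBoost as pluggable baselines,
  plus an `external` hook for predictions from any other model.
* **Synthetic data** — a generator that assembles valid molecules from ring
  templates and substituents, with planted scaffold structure, activity
  cliffs, near-cutoff edge groups, calibrated positive rates and optional
  (hetero-)Gaussian label noise, so the entire pipeline is testable offline
  against known ground truth.

Chemistry primitives are computed by RDKit through the `python` interpreter
on the PATH (see `SystemRequirements`); everything else is R.

## Worked example

```r
library(qsareval)

# A synthetic opioid-like activity dataset: ~600 molecules on 100 scaffolds,
# right-skewed pIC50, 30% positive rate at cutoff 6, planted cliffs.
out <- generate_activity_dataset(synthetic_preset("opioid-like", seed = 0))
d   <- out$dataset
d
#> <curated_dataset 'synthetic_seed0'> 584 molecules, task = regression

annotate_cliffs(d)
#> <ac_annotation> 100 scaffolds, 584 molecules; AC scaffolds 10 (10.0%),
#>                 AC molecules 223 (38.2%)
```

Ten percent of scaffolds are activity-cliff scaffolds, but they carry 38% of
the molecules — the burden that makes intra-scaffold generalization hard.

```r
fm   <- compute_representation("MorganBits", d)   # 584 x 2048 bits
m    <- random_split(d, seed = 0)
pred <- train_and_predict(model_spec("RF", "regression", seed = 0), fm, d, m)
evaluate_predictions(pred)
#>   metric value (n = 59 test molecules)
#>   RMSE      0.933
#>   MAE       0.694
#>   R2        0.292
#>   Pearson_R 0.625

views <- stratify_predictions(pred, annotate_cliffs(d))
#> AC test RMSE:     1.271  (n = 13)
#> non-AC test RMSE: 0.812  (n = 46)
```

The same raw predictions look substantially worse on the cliff-bearing
molecules — an error structure invisible in the pooled RMSE. The comparison
layer then works on per-seed metric vectors:

```r
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#> $U 0   $p 0.1   $method "exact"
```

## Command line

A thin CLI over the same functions lives at `inst/cli/qsareval`:

```sh
Rscript inst/cli/qsareval synth --preset opioid-like --seed 0 --out data.csv
Rscript inst/cli/qsareval run --in data.csv --models RF,XGBoost \
  --reps MorganBits --methods scaffold,random --seeds 30 --out-dir run/
```

See `vignettes/benchmark-methodology.Rmd` for the full methodology and the
design decisions behind it.
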