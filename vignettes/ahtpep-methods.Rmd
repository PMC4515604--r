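---
title: "Methods: length-stratified QSAR models for antihypertensive peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: length-stratified QSAR models for antihypertensive peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahtpep)
```

## The modelling problem

Food-derived peptides that inhibit angiotensin-converting enzyme (ACE) lower
blood pressure, and their reported lengths span everything from dipeptides to
15-mers and beyond. No single model serves that range well: for di- and
tripeptides enough quantitative activity data (IC50) exist to regress
activity directly, while longer peptides are better treated as a binary
AHT / non-AHT classification against background sequences. `ahtpep`
therefore stratifies by length into seven categories —

| category | lengths | task |
|---|---|---|
| `tiny_di`, `tiny_tri` | 2, 3 | support-vector regression of pIC50 |
| `small_tetra`, `small_penta`, `small_hexa` | 4, 5, 6 | binary classification |
| `medium` | 7–12 | binary classification |
| `large` | ≥ 13 | binary classification |

— and routes every peptide to its category's model. The `large` category is
deliberately unbounded above: all in-scope encoders are composition-based
and therefore length-agnostic, so there is no technical reason to cap input
length even though observed actives rarely exceed ~15 residues.

Activity is modelled on the pIC50 scale, `pIC50 = 6 - log10(IC50 in μM)`
(the negative decadic log of the molar IC50 — base 10 is the universal
pIC50 convention). This compresses the five-decade span of reported
activities (tripeptides down to 0.04 μM, dipeptides up to 17 000 μM, i.e.
pIC50 from about 1.77 to 7.40) into a regression-friendly range.

## Feature families

Four encoders produce the model inputs; each records a feature spec
(family, column names, parameters) on its output so a trained model can
refuse, or re-create, feature input:

* **Amino-acid composition (`encode_aac`)** — the percent of each of the 20
  residues in the peptide; rows sum to 100 exactly.
* **Atomic composition (`encode_atomic`)** — C/H/N/O/S atom counts summed
  over the residues and reported as fractions of the total atom count, so
  different lengths are comparable. Counts come from packaged molecular
  graphs of the 20 free amino acids (explicit hydrogens, fixed Kekulé
  forms), not from a transcribed table: the atom and bond accounting is
  recomputed from the graphs at load and verified in the tests. The default
  `residue_sum` mode uses free amino-acid counts; `dehydrated` removes one
  water (2 H + 1 O) per peptide bond for chemical correctness. The mode is
  part of the feature spec so models are never mixed across modes. Bond
  counts (total/single/double, as fractions) are an optional extension.
* **Scale descriptors (`encode_scales`)** — per-position rows of a
  20 × k amino-acid scale matrix, either averaged over positions or
  concatenated in sequence order for fixed-length categories. The built-in
  matrix is a synthetic placeholder assembled from properties the package
  computes itself (hydropathy, mass, charge, aromaticity, atom fractions,
  standardized); published multivariate scale sets are not redistributed,
  and any user matrix in the same 20-row format plugs in.
* **External descriptor tables (`load_descriptor_table`)** — thousands of
  cheminformatics descriptors are practical to compute only with dedicated
  software, so they are ingested from CSV keyed by sequence, aligned,
  validated cell-by-cell, and passed into the same pipeline. Constant
  columns are kept at ingestion; removing them is the selection stage's job.

## Descriptor selection

Large descriptor tables are pruned in three stages, in this order:

1. **`remove_useless`** — drops constant columns, columns whose most
   frequent value covers *strictly more than* `max_variance_pct` percent of
   rows (default 99; a column exactly at the threshold is kept), and
   integer-valued all-distinct columns in tables with more than 20 rows,
   which look like row identifiers. Continuous descriptors are all-distinct
   by nature and are never treated as identifiers — this is the one place
   the rule is narrower than a naive distinct-count test, and it is what
   keeps real descriptor tables intact.
2. **`best_first_search`** — forward best-first search maximizing Hall's
   CFS merit `k·r̄cf / sqrt(k + k(k−1)·r̄ff)`, computed from absolute
   Pearson correlations (binary targets coded 0/1). The search stops after
   5 consecutive non-improving expansions (lookup 1), the conventional
   defaults. Correlation-based merit on continuous features is a documented
   choice: attribute-selection tools that discretize and use symmetrical
   uncertainty will select somewhat different subsets, and exact
   replication of any particular tool is a non-goal. On instances small
   enough to enumerate (≤ 8 features) the search provably attains the
   exhaustive best-subset merit in the test suite.
3. **`f_stepping`** — backward elimination against a caller-supplied
   performance oracle (typically LOOCV R or accuracy): each feature is
   tentatively removed, the removal is kept iff the metric is unchanged or
   improved, otherwise the feature is restored. A single pass in the order
   features emerged from the search is the default; `until_stable` repeats
   until a pass removes nothing. The final metric can never be worse than
   the initial one, and the subset is never allowed to become empty (the
   best single feature is kept instead and flagged).

All tie-breaks anywhere in the pipeline are lexicographic on feature name,
so runs are bit-reproducible.

## SVM engine and evaluation

Models are RBF-kernel support-vector machines (libsvm via `e1071`):
ε-regression for tiny peptides, C-classification otherwise. Features are
standardized to zero mean / unit variance with statistics estimated on the
training data only; inside leave-one-out cross-validation the scaler is
refit in every fold, so no held-out information leaks into the fold's
model. LOOCV retrains literally n times and pools the n held-out
predictions before computing metrics (the standard pooled-LOOCV
convention).

* Regression: Pearson R and RMSE on pooled predictions.
* Classification: Sn, Sp, Acc (percent) and MCC from the pooled confusion
  table, plus a threshold sweep in 0.1 steps across the decision-score
  range (always including 0, the SVM margin). MCC is defined as 0 whenever
  a marginal is empty. The sweep also reports the accuracy-maximizing
  threshold and the most balanced one (minimal |Sn − Sp|); the deployed
  decision threshold of a tuned classifier is the accuracy-maximizing LOOCV
  threshold, stored with the model, with 0 as the untuned default.

Hyperparameters default to cost 10, γ 0.01, ε 0.1; `tune = TRUE` runs a
LOOCV grid search over cost {0.1, 1, 10, 100} × γ {0.001, 0.01, 0.1, 1}
(× ε {0.1, 0.5} for regression), ties resolved to the first grid point.
The original platform's SVM-light flags are not published, so these grids
are this package's own documented defaults and are recorded in the model
object, along with the scaler, feature spec, threshold, training-set hash
and seed.

Class balance is fixed at 1:1 — `sample_negatives` draws exactly as many
background fragments as there are positives, excluding any fragment present
in the positive set and any fragment with non-natural letters (X, B, Z, U
in real proteomes), uniformly over all (protein, offset) positions with a
fixed seed. Distinct fragments are preferred; duplicates appear only when
the unique pool is exhausted, with a warning.

## Application modes

* **Design (`generate_analogs`/`design_analogs`)** — all 19·L
  single-substitution analogs of an L-mer, enumerated position-major and
  alphabetically, scored with the parent's category model. Terminal
  insertions/deletions are excluded on purpose: they change the length
  category and hence the model, making parent and analog scores
  incomparable.
* **Screening (`screen_library`)** — routes a mixed-length library,
  attaches the physicochemical panel, ranks within category; invalid
  records are set aside in an `errors` attribute, never silently dropped.
* **Scanning (`scan_protein`)** — all N−w+1 overlapping windows per
  requested length w (1-based inclusive coordinates, the convention
  biologists expect in reports). Overlapping above-threshold windows are
  reported individually; merging into regions is left to the caller since
  no canonical merge rule exists.

The physicochemical panel reports length; monoisotopic molecular weight
(residue masses from the packaged atom counts, minus one water per peptide
bond); an integer net charge at pH 7 (+1 per K/R, −1 per D/E, +1/−1 for the
termini, histidine neutral by default and configurable — a deliberate
simplification of the Henderson–Hasselbalch picture, adequate for a
sortable report column); mean Kyte–Doolittle hydropathy; and the atom
fractions.

## Synthetic data: what it emulates and what it does not

Real curated activity data cannot be redistributed here, so
`synthetic-data.R` generates datasets with the statistical structure the
models assume:

* `builtin_profiles()` carries the percent residue composition of each AHT
  length class and of background peptides; profiles are renormalized to sum
  exactly to 1 (printed percentages carry rounding error). The key biases —
  proline enrichment in all AHT classes, Trp/Tyr/Gly enrichment in
  dipeptides — are what composition classifiers learn.
* `sample_peptides()` draws residues i.i.d. from a profile. Positional
  structure is deliberately absent: every in-scope encoder is either
  composition-based or position-concatenated without inter-position
  dependence, so i.i.d. sampling exercises exactly what the models can see.
  Real peptides have positional and neighbour dependencies (e.g. C-terminal
  Pro/aromatic preferences for ACE binding); passing tests on synthetic
  data therefore demonstrates pipeline correctness and signal recovery,
  not real-world predictive accuracy.
* `make_classification_set()` builds balanced, class-disjoint sets;
  `make_regression_set()` plants a known linear model on composition
  features (`pIC50 = w·x + b + N(0, σ)`) so regression recovery is
  checkable against ground truth.

Fixture sizes were chosen as the smallest that make the statistical checks
stable: classification sets of 200 per class at length 10 (the midpoint of
the medium band), regression sets of n = 150 dipeptides, LOOCV-oracle
instances of n ≤ 15, and 100 random instances of ≤ 8 features for the
exhaustive-search comparison.

An information-theoretic point the test suite makes explicit: with i.i.d.
sampling from the printed composition profiles, the best possible
classifier of medium-length peptides is the per-residue log-likelihood
ratio, and its Monte-Carlo accuracy (computed by `scripts/acceptance.R` as
`medium_vs_background_bayes_bound_acc`) sits around the high 70s percent
at length 10. Composition-profile separation alone therefore cannot push a
medium-length classifier into the mid-80s accuracies reported for models
trained on real curated peptides; real data evidently contain structure
beyond single-residue composition. The corresponding recovery check in the
test suite asserts the stricter published-style bar and is expected to
fail under these synthetic conditions; the null-profile calibration
(identical profiles ⇒ chance-level accuracy) and the noiseless planted
regression (LOOCV R essentially 1) pass.

## Numerical and degenerate-input choices

* Peptides shorter than 2 residues and non-natural residues are hard,
  classed errors naming the offending position; batch APIs collect
  per-record errors instead of failing wholesale.
* Duplicate sequences in a dataset keep their first occurrence (the merge
  rule for conflicting activity records in the source databases is
  unknown); the dropped records are named in a warning.
* `cfs_merit` refuses zero-variance features (correlation undefined) rather
  than imputing 0.
* Regression R is defined as 0 when the predictions are constant and
  refuses constant truth.
* Constant feature columns pass through the scaler untouched (unit scale).
* Decision scores are re-oriented so that larger always means the positive
  class regardless of libsvm's internal label order.
* All randomness flows through explicit integer seeds; SVM fitting itself
  is deterministic.

## Known limitations

* Predictions inherit every limitation of the training data the user
  supplies; the shipped synthetic generator is a test harness, not a
  substitute for curated activity data.
* External descriptors are ingestion-only; the package does not compute 3-D
  or fingerprint descriptors.
* The built-in scale matrix is a synthetic stand-in; users wanting
  published z-scale/G-scale-style encodings must supply the matrix.
* The integer charge model ignores pKa shifts; it is a report column, not a
  titration.
* Post-translationally modified and D-amino-acid peptides are out of scope.
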