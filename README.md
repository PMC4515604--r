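# ahtpep

Length-stratified QSAR modelling of antihypertensive (ACE-inhibitory)
peptides in R.

Peptides that inhibit angiotensin-converting enzyme lower blood pressure,
and candidates come from everywhere: milk, egg, fish and plant protein
hydrolysates, synthetic analog series, whole proteins waiting to be
scanned. Their reported lengths run from 2 residues upward, which is too
wide a range for one model. `ahtpep` routes every peptide by length:
di- and tripeptides get support-vector **regression** of pIC50
(`pIC50 = 6 − log10(IC50 in μM)`), and peptides of four residues or more
get binary AHT / non-AHT **classification** against background sequences,
with separate models for tetra/penta/hexapeptides, medium (7–12) and large
(≥ 13) peptides. It is aimed at peptide-QSAR practitioners who want a
scriptable, testable version of this workflow: train on their own activity
tables, evaluate honestly by leave-one-out cross-validation, then design
analogs, screen libraries, and scan proteins.

What is in the box:

* **Encoders** — amino-acid composition (percent 20-vector); atomic
  composition (C/H/N/O/S and bond fractions, derived from packaged
  explicit-hydrogen molecular graphs of the 20 amino acids, not a
  transcribed table); pluggable 20 × k amino-acid scale matrices;
  ingestion of externally computed descriptor tables (e.g. PaDEL output).
* **Descriptor selection** — useless-column removal, correlation-based
  (CFS) subset search under forward best-first
  (merit `k·r̄cf / √(k + k(k−1)·r̄ff)`), and F-stepping backward
  elimination against a cross-validated performance oracle.
* **SVM engine** — RBF-kernel ε-regression / C-classification (libsvm via
  `e1071`), leak-free per-fold standardization, LOOCV, Pearson R / RMSE,
  Sn / Sp / Acc / MCC with threshold-wise tables, and the length-category
  model router.
* **Application modes** — all-19L single-substitution analog design,
  library screening with a physicochemical panel, sliding-window protein
  scanning, and 1:1 background negative sampling with exclusions.
* **Synthetic data** — composition-profile peptide generators and planted
  linear activity models, so the entire pipeline is testable offline.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on models and evaluations, `autoplot()` on reports.

## Worked example

Train a medium-peptide classifier on a synthetic composition-biased
dataset, evaluate it, and screen three candidate 10-mers:

```r
library(ahtpep)
library(dplyr)

train  <- make_classification_set("medium", "non_aht",
                                  length = 10, n_per_class = 60, seed = 42)
feats  <- encode_aac(train)
model  <- aht_train(feats, "label", category = "medium",
                    hyper = list(cost = 1, gamma = 0.05))
bundle <- aht_bundle(model)

glance(aht_loocv(feats, "label", hyper = list(cost = 1, gamma = 0.05)))
#> # A tibble: 1 × 6
#>   task               n    sn    sp   acc   mcc
#>   <chr>          <int> <dbl> <dbl> <dbl> <dbl>
#> 1 classification   120    70  83.3  76.7 0.538

screen_library(c("IPPAPLPWYV", "GDSEEESNKQ", "VYPFPGPIPN"), bundle) |>
  select(sequence, category, score, call, mol_weight, net_charge, hydropathy)
#> # A tibble: 3 × 7
#>   sequence   category  score  call mol_weight net_charge hydropathy
#>   <chr>      <chr>     <dbl> <int>      <dbl>      <dbl>      <dbl>
#> 1 VYPFPGPIPN medium    1.91      1      1100.          0    -0.0100
#> 2 IPPAPLPWYV medium    1.48      1      1152.          0     0.57
#> 3 GDSEEESNKQ medium   -0.608     0      1121.         -3    -2.69
```

The LOOCV glance says the classifier recovers the proline/aromatic
composition bias of the positive class at ~77 % pooled accuracy (MCC 0.54)
on 120 held-out predictions. In the screen, the two proline-rich 10-mers
score above the decision threshold (`call = 1`, predicted AHT) while the
acidic, hydrophilic one scores below it; the panel columns (monoisotopic
weight, integer net charge at pH 7, mean Kyte–Doolittle hydropathy) are the
sortable properties reported alongside every prediction.

The chemistry layer is recomputed, not transcribed — e.g. tryptophan's
free-amino-acid graph yields:

```r
residue_atoms("W")
#> # A tibble: 1 × 9
#>   residue     C     H     N     O     S total_bonds single_bonds double_bonds
#>   <chr>   <int> <int> <int> <int> <int>       <int>        <int>        <int>
#> 1 W          11    12     2     2     0          28           23            5
```

A thin command-line front end over the same functions lives at
`inst/scripts/ahtpep.R` (subcommands `train`, `predict`, `design`,
`screen`, `scan`, `make-fixtures`).

See `vignettes/ahtpep-methods.Rmd` for the full model description,
parameter defaults, selection pipeline, and the design rationale behind the
synthetic-data generator.

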