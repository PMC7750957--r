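# swisol

Sequence-only prediction of recombinant protein solubility in *Escherichia
coli* via the **Solubility-Weighted Index (SWI)**.

Roughly half of successfully expressed recombinant proteins turn out
insoluble, and triaging constructs before they reach the bench is a standard
step in structural biology and protein engineering. Global structural
flexibility — modeled from normalized crystallographic B-factors — turns out
to be a strong sequence-only predictor of solubility, and optimizing those
B-factor values against experimental solubility outcomes yields a set of 20
per-residue weights whose plain arithmetic mean over a sequence,

```
SWI = <W_i>
```

is a fast, composition-based solubility score. A logistic calibration

```
P(soluble) = 1 / (1 + exp(-(a * SWI + b))),   a = 81.05812, b = -62.7775
```

maps SWI to a probability of solubility. The package is aimed at protein
biochemists planning expression constructs (choosing domains, truncations and
solubility tags) and at method developers who want the full training pipeline
in a reproducible, scriptable form.

## What the package provides

* **Scoring** — SWI, probability of solubility, local flexibility profiles
  (9-residue sliding window over normalized B-factors, coefficients
  1, 0.8125, 0.625, 0.4375, 0.25, divisor 5.25), global flexibility
  (windowed or plain mean) and Kyte–Doolittle GRAVY:
  `swi()`, `probability_of_solubility()`, `flexibility_profile()`,
  `global_flexibility()`, `gravy()`, `solubility_report()`.
* **Residue scales** — the final SWI weights, four published normalized
  B-factor sets (Smith, Vihinen, Bhaskaran–Ponnuswamy, Karplus–Schulz) and
  Kyte–Doolittle hydropathy, shipped as JSON data files:
  `get_scale()`, `load_weights()`, `save_weights()`.
* **Training** — the weight-derivation pipeline: homology-aware
  cross-validation folds built from sequence-similarity clusters,
  class-balanced bootstrap resampling, derivative-free (Nelder–Mead) AUC
  maximization, per-fold weight averaging and logistic recalibration:
  `train_swi()`, `auc()`, `build_folds()`, `fit_logistic()`,
  `greedy_cluster()`.
* **Enrichment** — per-residue log2 bit scores of a sequence group against a
  background, and the 12 000-sequence random control set:
  `bit_scores()`, `random_sequences()`.
* **Region optimization** — simulated-annealing extension of a seed region to
  maximize its probability of solubility, and solubility-tag fusion scoring:
  `anneal_region()`, `score_with_tag()`.
* **Synthetic data** — labeled, clustered datasets with a planted weight
  vector for end-to-end validation: `generate_dataset()`.
* **CLI** — `swisol_main()` plus a launcher script (`inst/exec/swisol`)
  exposing `score`, `profile`, `train`, `enrich`, `simulate-random`,
  `simulate`, `optimize-region` and `fuse`.

## Worked example

```r
library(swisol)

seq <- "MRGSHHHHHHTDPALRAMKVLWAALLVTFLAGCQA"
solubility_report(seq, id = "demo")
#>     id start end length       swi probability flexibility_window flexibility_mean      gravy
#> 1 demo     1  35     35 0.7750751   0.5121562          0.9719603        0.9755429 0.07714286
```

The construct's SWI (0.775) sits almost exactly at the calibration midpoint
(-b/a = 0.7745), so its predicted probability of solubility is ~0.51 — a
borderline construct. Its mean normalized B-factor (0.976) and near-zero
GRAVY (0.077) tell the same story: average flexibility, no strong
hydrophilicity. Can an N-terminal solubility tag help?

```r
score_with_tag(tag = "MKKDDKKEDE", target = seq, terminus = "N")$probability
#> [1] 0.9139658
```

The charged tag raises the fusion's SWI to a 0.92 probability of solubility.
Region-level optimization works the same way: `anneal_region()` extends a
domain's boundaries to maximize the probability, returning candidate regions
ranked by probability.

To retrain the weights on your own labeled data from the command line:

```sh
swisol train --fasta proteins.fasta --labels labels.tsv \
  --out-prefix run1 --seed 1 --folds 10 --bootstraps 1000 --per-class 1000
```

which writes final and per-fold weight JSON files, a fitted calibration and a
per-fold train/test AUC report.

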