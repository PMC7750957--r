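---
title: "The Solubility-Weighted Index: model, training pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Solubility-Weighted Index: model, training pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swisol)
```

## The model

Protein solubility in an *E. coli* expression host correlates strongly with
global structural flexibility, which can be estimated from sequence alone
using normalized crystallographic B-factors: per-residue averages of atomic
displacement, rescaled so they apply to sequences without solved structures.

Two flexibility summaries are supported. The **windowed** form averages each
residue's neighborhood with a 9-residue window:

$$f_i = \frac{1}{5.25}\left[B_i + 0.8125 (B_{i-1} + B_{i+1}) + 0.625 (B_{i-2} + B_{i+2}) + 0.4375 (B_{i-3} + B_{i+3}) + 0.25 (B_{i-4} + B_{i+4})\right]$$

and global flexibility $F$ is the mean of the $f_i$. Because the nine window
coefficients sum to the divisor 5.25, each $f_i$ is a convex combination of B
values — so a homopolymer's profile equals its residue's B value, and every
profile is bounded by the scale extremes. The **simplified** form drops the
window entirely: $F' = \langle B_i \rangle$, a zeroth-order (composition-only)
summary. The two are nearly rank-identical (the package asserts Spearman
$\rho > 0.95$ on 1000 random sequences of length 100–1000), which is what
justifies composition-based scoring.

The **Solubility-Weighted Index** replaces the B-factors with weights $W_i$
optimized against experimental solubility outcomes:

$$\mathrm{SWI} = \langle W_i \rangle,$$

and a logistic calibration maps SWI to a probability of solubility:

$$P(\text{soluble}) = \frac{1}{1 + e^{-(a\,\mathrm{SWI} + b)}},
\qquad a = 81.05812,\; b = -62.7775.$$

The calibration midpoint is at SWI $= -b/a \approx 0.7745$. The slope is
steep: SWI values of natural-length proteins occupy a narrow band (the mean
of a few hundred weights drawn from a table whose spread is ~0.12), so small
SWI differences are biologically meaningful and the logistic must amplify
them.

Assumptions worth keeping in mind: the score is purely compositional
(position-independent), the calibration is specific to *E. coli* expression
with the weights it was fitted alongside, and the probability is conditional
on successful expression — it says nothing about whether the protein
expresses at all.

## Residue scales

Six scales ship as JSON data files (`get_scale()`, `list_scales()`): the
final SWI weights; the Smith et al. (2003) normalized B-factors that serve as
the training pipeline's initial weights; three further published flexibility
scales (Vihinen et al. 1994 — the scale Biopython's ProtParam uses;
Bhaskaran–Ponnuswamy 1988; Karplus–Schulz 1985); and Kyte–Doolittle
hydropathy for GRAVY. In the final weights, charged residues (D, E, K) carry
the highest values and cysteine the lowest — consistent with disulfide-bond
formation failing in standard *E. coli* hosts. The shipped tables are
read-only at run time; user weight sets enter through `load_weights()`, and
`save_weights()` serializes values as 17-digit decimal strings so files
round-trip doubles exactly.

## The training pipeline

`train_swi()` reproduces the weight-derivation procedure:

1. **Homology-aware folds.** Sequences arrive grouped into similarity
   clusters (externally computed, or via the fixture-grade
   `greedy_cluster()`). Whole clusters are packed into folds
   largest-cluster-first into the currently smallest fold, with the seed
   breaking ties. The original procedure grouped clusters into subsets
   manually; a deterministic greedy packing was chosen here so fold
   construction is reproducible. A leakage assertion inside `train_swi()`
   verifies that no cluster ever appears on both sides of a split.
2. **Class-balanced bootstraps.** Each fold's training complement is
   resampled with replacement, `n_per_class` draws per class (default 1000 +
   1000), guarding the AUC objective against class imbalance and repeated
   near-identical sequences.
3. **AUC maximization.** AUC is non-differentiable, so each resample is
   optimized by Nelder–Mead (via `stats::optim`) over the 20 weight values,
   starting from the initial weights (Smith et al. by default; every
   optimization is cold-started). Convergence: relative simplex tolerance
   1e-6 or 5000 iterations; a monotone-improvement guard returns the initial
   vector in the rare case the optimizer ends below it. AUC itself is the
   rank-based Mann–Whitney statistic with half-credit for ties, which the
   test suite pins against an $O(n^2)$ pairwise oracle.
4. **Averaging.** The per-fold mean of the bootstrap optima gives $V_k$;
   the final weights are the mean of the $V_k$. Aggregation is deliberately
   per-fold-then-across-folds, not pooled.

**Non-identifiability.** AUC is invariant under shifting all weights by a
constant and scaling by a positive constant, so trained weights are only
identified up to an affine transform. No normalization is imposed; instead a
freshly trained weight set should travel with its own logistic calibration
(`fit_logistic()`, a capped-iteration ML fit that flags quasi-complete
separation instead of returning runaway coefficients).

## Region annealing

`anneal_region()` maximizes the probability of solubility of a region by
stochastic boundary moves. Candidate regions always contain the seed region:
boundary displacements of up to 3 residues may push outward or step back
toward the seed, but never inside it (an `allow_shrink` flag lifts that
restriction). The first implementation used strictly-outward moves; that
makes every accepted downhill move irreversible — a ratchet that overshoots
the optimum and cannot return — and it agreed with exhaustive search on only
a small fraction of short test sequences, so reversible-within-the-extension
moves are the default.

Acceptance follows Metropolis: improvements always, deteriorations with
probability $e^{\Delta p / T}$ under geometric cooling ($T \leftarrow 0.95\,T$,
50 proposals per temperature, stop below $10^{-4}$). The initial temperature
(0.25) is matched to the objective's scale: under the steep published
calibration a single boundary residue can change the probability by a few
tenths, so a colder start would reject essentially every downhill move and
degenerate into greedy hill-climbing. The best-ever region is tracked over
all *evaluated* candidates (not only accepted ones), ties broken toward
shorter regions, and the best-first result is guaranteed not to fall below
the seed region's probability. On sequences of up to 40 residues the
optimizer is checked against exhaustive enumeration of all extensions.

Tag fusion (`score_with_tag()`) is pure composition algebra: the fusion SWI
is the length-weighted mean of tag and target SWI, identical for N- and
C-terminal placement.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the pipeline needs:
sequence families descended from i.i.d. uniform-composition ancestors by
point substitutions (default 20 families × 20 members, lengths 100–300,
substitution rate 0.1), with per-sequence binary labels drawn through a
logistic link on the planted-weight SWI. Labels are per-sequence, not
per-family, so families can be label-mixed, as a minority of real similarity
clusters are.

The default link slope is 800 with the intercept centered at the mean planted
weight: at ancestor length ~200 the between-sequence SWI standard deviation
is roughly 0.008, so the slope puts about six logistic standard deviations
between typical low- and high-SWI sequences — a strong but noisy link,
chosen so that recovery is demanding (label noise exists) yet feasible at
desk scale. The planted weights default to the Smith scale.

What the generator does **not** emulate: indels, domain architecture,
realistic amino-acid composition, length–label confounding, or continuous
solubility percentages (the link probability is exported as a continuous
hook). Passing recovery tests therefore demonstrates that the pipeline
recovers a planted compositional signal under clustered, noisy labels — not
that it would reach any particular AUC on real expression data.

## Validation problem sizes

The packaged checks run the pipeline at sizes chosen to exercise every code
path while staying desk-scale: parameter recovery uses 400 sequences with 3
folds × 20 bootstraps × 100 per class from 30%-perturbed initial weights
(asserting Spearman ≥ 0.8 against the planted weights, mean test AUC ≥ 0.85,
and per-fold improvement over the initial weights); the annealing check runs
100 seeded optimizations against exhaustive search; the AUC oracle comparison
runs 500 random instances up to n = 200; the random-control generator is run
at its full default grid (12 000 sequences).

## Numerical choices

* The logistic is evaluated in a two-branch form that only exponentiates
  non-positive arguments: it saturates cleanly to 0/1 and never overflows.
* Window coefficients (1, 0.8125, 0.625, 0.4375, 0.25) are exact binary
  fractions; profile convolution uses `stats::filter`, and means use R's
  long-double accumulating `mean()`, keeping scores reproducible across
  platforms at ~1e-15.
* Probability comparisons in tests use 1e-12 tolerances: the steep
  calibration amplifies last-ulp SWI differences (e.g. cumulative-sum versus
  direct-mean evaluation of the same region) by a factor of ~80.
* All stochastic components (fold tie-breaks, bootstraps, annealing,
  generators) take explicit integer seeds and restore the caller's RNG
  state; identical seeds give identical results to the byte.

## Limitations

* The score is compositional: permuting a sequence never changes SWI, so
  position-dependent solubility effects (signal peptides, N-terminal codon
  effects, proteolytic cleavage of tags) are invisible.
* The shipped calibration applies to the shipped final weights only; scoring
  with other scales requires refitting.
* `greedy_cluster()` is a deterministic k-mer stand-in adequate for building
  test fixtures, not a replacement for a production clustering tool.
* Nonstandard residues have no weights; the explicit `error`/`drop`/`reject`
  policies in `read_fasta()` make the choice visible rather than guessing.
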