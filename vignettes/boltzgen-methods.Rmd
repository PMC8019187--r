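---
title: "Generative models and disclosure metrics for binary SNP data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative models and disclosure metrics for binary SNP data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boltzgen)
```

`boltzgen` generates synthetic binary patient data — haploid SNP
minor-allele indicators, or any other 0/1 feature matrix — and measures
how useful and how disclosive the synthetic data are. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the numerical and design choices made where more than one
reasonable option existed.

## The setting

The data container throughout is a `binary_dataset`: samples (patients or
chromosomes) in rows, binary variables in columns, with unique names on
both axes. Missing values are rejected at read time; the intended inputs
are complete haploid panels. The multi-site setting is simulated
in-process: the training rows are divided into consecutive, equally sized
shares (`split_sites()`), one generator is fitted per share, each share
generates as many synthetic rows as it holds, and the pooled synthetic
dataset is evaluated. No networking or federation protocol is involved;
the sites exist to study how per-site sample size affects the generators.

## Boltzmann machines

A restricted Boltzmann machine (RBM) places a Boltzmann distribution over
binary visible units $v$ and hidden units $h$:

$$p(v,h) = \frac{e^{-E(v,h)}}{Z}, \qquad
  E(v,h) = -v^\top W h - a^\top v - b^\top h, \qquad
  Z = \sum_{v,h} e^{-E(v,h)}.$$

The bipartite connection graph makes both conditionals factorise,
$p(h_j = 1 \mid v) = \sigma(b_j + \sum_i v_i W_{ij})$ and symmetrically
for the visible layer, which is what makes block Gibbs sampling and
contrastive divergence practical. A deep Boltzmann machine (DBM) stacks
$L$ layers with the analogous layered energy; layers of equal parity are
conditionally independent given the others, so Gibbs sampling alternates
between the odd and even layers of the full network. Conditional
sampling — clamping chosen visible variables and sampling the rest — falls
out of the same scheme: clamped columns are simply reset after every
visible update.

Assumptions worth stating: all units are binary (no Gaussian visible
units); the model is fully observed at the visible layer; and the data
rows are treated as exchangeable. The models are *not* given the
case/control labels of the simulated design — any label-related structure
they reproduce has been learned from the joint distribution alone.

### Training

RBMs are trained by CD-k stochastic gradient ascent: for each minibatch
the data-driven statistics $\langle v h^\top \rangle$ (hidden units as
probabilities) are compared against the statistics after $k$ alternating
Gibbs steps started from the data (binary samples throughout, except the
final hidden probabilities). DBMs are trained in two stages:

1. **Greedy layer-wise pre-training** (`pretrain_stack()`): RBM 1 is
   trained on the data, each further RBM on the hidden activation
   *probabilities* (not samples — lower variance at the small per-site
   sample sizes targeted here) of the one below. Because in the assembled
   undirected network every interior layer receives input from both
   sides, the RBMs are trained with compensated input: the first doubles
   its visible-to-hidden input, the last its hidden-to-visible input, and
   interior RBMs double both sides and have their weights halved on
   assembly (`stack_to_dbm()`); interior biases are the mean of the two
   available estimates. A single-layer "stack" has no doubling, so it is
   trained exactly like `fit_rbm()`.
2. **Mean-field fine-tuning** (`finetune_dbm()`): stochastic gradient
   ascent on the variational lower bound. The positive phase runs
   fully factorised mean-field inference per minibatch (default 10
   sweeps, convergence tolerance 1e-6); the negative phase uses
   persistent block-Gibbs chains (default 5 chains, 5 sweeps per update,
   both configurable). With `epochs = 0` the converted stack is returned
   unchanged, giving a pre-training-only model.

Weights are initialised $\mathcal N(0, 0.01^2)$, biases at zero; the
optimiser is plain SGD without momentum or weight decay. These choices
keep the hyperparameter surface to the one exposed by `train_config()`.

### Hyperparameters

| Parameter | Meaning | Default |
|---|---|---|
| `nhiddens` | hidden layer sizes (one entry per layer) | `c(50, 10)` |
| `epochspretraining` | CD epochs per layer | 30 |
| `learningratepretraining` | CD learning rate | 0.001 |
| `epochs` | fine-tuning epochs | 30 |
| `learningrate` | fine-tuning learning rate | 0.1 |
| `batchsizepretraining`, `batchsize` | minibatch sizes | 20 |
| `cdsteps` | Gibbs steps in CD-k | 1 |

The defaults are the settings of the package's simulated SNP experiments
(50-variable data, 500 samples): two hidden layers of 50 and 10 nodes, 30
pre-training epochs at rate 0.001 and 30 fine-tuning epochs at rate 0.1.
Learning rates are unitless multipliers on the per-minibatch gradient;
epochs count full passes over the data. Per-layer overrides are available
through `layer_config()`. Gibbs sampling defaults to a burn-in of 50
sweeps with an independent chain per synthetic sample — small models of
this size mix quickly, and independent chains avoid autocorrelation
between synthetic rows at modest cost; both are configurable where rigor
demands it.

### Monitoring and likelihood evaluation

The partition function is intractable beyond toy sizes, so three
evaluation routes are provided:

- **Reconstruction error**: mean squared Euclidean distance between each
  sample and its one-step hidden-then-visible reconstruction (both passes
  with probabilities). Cheap, tracks the likelihood well, recorded once
  per epoch when monitoring is requested. "Distance" is not pinned down
  further by convention; the squared Euclidean form was chosen because it
  is smooth and comparable across epochs.
- **Exact enumeration** (`exact_log_partition()`,
  `exact_loglikelihood()`): sums over all configurations with the hidden
  (for DBMs: odd) layers collapsed analytically via the
  $\prod_j (1 + e^{x_j})$ identity. Guarded by a cap of 24 total units.
- **Annealed importance sampling** (`ais_log_partition()` and the
  likelihood functions built on it): anneals from a base model with the
  target's biases but zero weights — a lower-variance path than the
  uniform base — along equally spaced inverse temperatures applied to the
  weights only. Defaults: 100 temperatures, 100 particles, chosen to be
  accurate within seconds at the model sizes above. The standard error is
  a delta-method estimate on the log of the mean importance weight; it is
  the package's uncertainty convention for the "within 3 standard errors"
  checks in the test suite. For DBMs the annealing state is the even
  layers with odd layers summed out; the per-sample DBM likelihood
  (`dbm_loglikelihood()`) runs one additional AIS pass per sample with
  the visible layer clamped to that sample, which is one of several ways
  to estimate the unnormalised marginal and the one adopted here. The
  variational lower bound (`dbm_logproblowerbound()`) is the mean-field
  expected negative energy plus the mean-field entropy minus the AIS
  $\log \hat Z$; it is exact for zero-weight models.

## Baseline generators

**Independent marginals (IM)** stores each variable's empirical frequency
and samples independently — deliberately structure-free.

**MICE (generative use)** factorises the joint along a uniformly random
variable order: the first variable by its frequency, each later one by a
logistic regression on its predecessors. Candidate predictors are added
consecutively in the order; a candidate whose inclusion does not raise the
rank of the design matrix (QR rank test, tolerance 1e-8) is "collinear"
and excluded from that and every later regression — a deterministic,
implementation-independent reading of collinearity. A constant outcome is
recorded as a constant prediction without fitting. Regressions are fitted
by maximum likelihood (`stats::glm`); binary data at small $n$ separate
easily, so when the MLE diverges (non-convergence, `NA` or coefficients
beyond 15 in absolute value) the fit falls back to an internal L2-ridge
Newton solver (penalty 1e-4, intercept unpenalised) and coefficients are
clipped to $|\beta| \le 15$. One fitted model is reused for all sampling
batches. Only the generative use of MICE is implemented; multiple
imputation of missing data is out of scope.

## Utility and disclosure metrics

The utility metric compares pairwise association structure: for each pair
of variables the $2 \times 2$ cross table is formed, **zero cells only**
are replaced by 0.5 so every odds ratio is finite, and
`odds_ratio_distance()` returns the RMSE between the strictly lower
triangles of the two log-odds-ratio matrices. Odds ratios rather than
correlations because they are the natural association scale for binary
SNP data and connect directly to logistic-regression effect sizes.

The proportion of overfitting,
$(d(x_{gen}, x_{val}) - d(x_{gen}, x_{train})) / d(x_{gen}, x_{val})$, is
positive when the generator reproduces its training data better than
held-out data and is bounded above by 1; a zero denominator (identical
log-odds structure, essentially impossible for distinct finite datasets)
is guarded with an explicit error.

The membership attack guesses that a probe row was a training sample iff
some generated row lies within Hamming distance $t$. Per threshold the
confusion counts over the training rows (positives) and an equally sized
test set (negatives) give precision and sensitivity. The threshold grid
defaults to 0–10; no single "right" distance exists, so the whole curve
is reported. Precision with zero positive guesses is reported as missing,
never as zero, and missing values are excluded from medians — silent
zeros would bias the summaries exactly where the attack is weakest.

## The multi-site experiment

`run_experiment()` crosses datasets × generator types × site counts. Per
cell: split the training rows into consecutive equal shares, run a
hyperparameter search over `n_inits` random initialisations and the
training epoch axis (up to `epoch_cap`), select by $d(x_{gen},
x_{test})$, then score the selected pooled data against validation data.
Each site generates exactly its share size, so the pooled synthetic set
matches the total training size — the unique choice consistent with equal
shares. Per-site and per-initialisation seeds are derived
deterministically from the master seed (independent initialisations per
site), so the entire experiment is reproducible from one integer, and
cells are independent of each other. Rather than evaluating literally
every epoch, the fine-tuning trajectory is checkpointed at `n_checkpoints`
(default 20) evenly spaced epochs; setting `n_checkpoints = epoch_cap`
restores full resolution, and the evaluated grid is returned with the
result. Summary quantiles use the type-7 (linear interpolation)
convention, recorded in the result object.

## The synthetic-data generators

`simulate_snp_sets()` emulates the package's study design: 500 samples ×
50 variables, iid Bernoulli(0.1) background noise, an equal case/control
split, and five "SNP sets" of five consecutive variables at evenly spaced
starts (columns 1–5, 11–15, …). Each case activates each block
independently with probability 0.5 — the design's block pattern varies
from case to case — and activation overwrites the noise with ones;
controls carry noise only. Both readings of the block pattern are one
parameter away: `set_activation_p = 1` makes every case carry every
block. Labels are assigned in random row order so that a consecutive site
split mixes cases and controls at every site, as a random patient
ordering would in practice.

What this generator does *not* emulate: linkage disequilibrium decay,
coalescent ancestry, diploid genotypes, allele-frequency spectra, or any
non-block interaction structure. Tests passing on this fixture therefore
show that the pipeline learns and preserves planted co-occurrence
structure at realistic noise levels — not that a DBM captures the full
correlation structure of real genomes. `simulate_iid_bernoulli()`
provides the null fixture (no structure at all), and
`simulate_logistic_chain()` generates from exactly the model family MICE
fits, for parameter-recovery tests with known ground truth.

## Numerical choices and degenerate inputs

- Column positions are 1-based and inclusive throughout (`select_locus`),
  the R convention; the CLI accepts the same.
- The MAF filter is strictly "below": a frequency exactly at the
  threshold is kept.
- Every stochastic function takes an explicit seed and restores the
  caller's RNG state; derived seeds stay below $2^{31}$.
- `log(1 + e^x)` is computed via a softplus guard to avoid overflow at
  saturated biases; log-sum-exp is max-stabilised.
- Degenerate inputs are errors with typed condition classes: empty
  datasets where a fit needs data, dimension mismatches, out-of-range
  clamping indices, over-cap exact enumeration, zero utility distance in
  the overfitting ratio. Unequal train/test sizes in the attack warn and
  proceed, since the 0.5 precision baseline shifts.
- Model files are JSON containers written at full precision (17
  significant digits), so write/read round trips are exact.

## Problem sizes in the test suite

The unit and acceptance tests run the full pipelines at the design sizes
(500 × 50 data, two hidden layers of 50 and 10, 30 + 30 epochs) and use
reduced grids elsewhere: enumeration oracles at 2–4 units per layer, AIS
checks at 100 temperatures × 100 particles with 100 seeded replicates,
attack and recovery checks at $n$ between 5\,000 and 100\,000 draws.
These sizes were chosen so the statistical tolerances in the tests
(binomial confidence bands, 3-standard-error brackets, total-variation
bounds) are actually discriminating at the given replicate counts.

## Known limitations

- Binary units only; no continuous or count data.
- No persistent-CD, momentum or adaptive optimisers; very deep stacks
  would likely need them.
- Mean-field inference is approximate; its means are only close to exact
  posterior marginals under weak coupling (the tests document a 0.05
  tolerance at small sizes).
- The two-dimensional latent representation requires a 2-node top layer
  by contract; there is no projection fallback for wider top layers.
- Partitioned layer architectures and differential-privacy mechanisms are
  not implemented; the disclosure metrics here (overfitting proportion,
  membership attack) are empirical, not worst-case guarantees.
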