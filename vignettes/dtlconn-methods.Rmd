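---
title: "Transfer learning for small-sample connectome classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for small-sample connectome classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtlconn)
```

## The problem

Whole-brain functional connectomes — matrices of Pearson correlations
between regional resting-state BOLD time series — are high-dimensional
(4,005 edge features for the 90-region AAL parcellation) while clinical
cohorts are small (tens of subjects per group). Deep networks fit such data
badly from random initializations, and the conventional remedy, greedy
unsupervised pretraining, needs data the target study does not have.
`dtlconn` implements the transfer-learning alternative: learn what healthy
connectomes look like *once*, offline, from a large corpus of healthy
subjects, and re-use that representation to initialize each new
small-sample disease classifier.

## Model

### Sparse autoencoder

Each building block is an L2-regularized sparse autoencoder. For input
$x \in \mathbb{R}^n$, hidden code $z = \sigma(W_1 x + b_1)$ with
$\sigma$ the logistic sigmoid, and reconstruction
$\hat{x} = W_2 z + b_2$. The training cost over $p$ samples is

$$E = \frac{1}{p}\sum_{j=1}^{p}\sum_{i=1}^{n}(\hat{x}_{ij}-x_{ij})^2
  + \lambda\,\tfrac12\sum_{i,j} (W_1)_{ij}^2
  + \beta \sum_{i=1}^{k}\mathrm{KL}(\rho \,\|\, \rho'_i),$$

where $\rho'_i$ is the mean activation of hidden unit $i$ over the sample
and $\mathrm{KL}(\rho\|\rho') = \rho\ln(\rho/\rho') +
(1-\rho)\ln\!\big((1-\rho)/(1-\rho')\big)$ (natural logarithm). The L2
penalty acts on encoding weights only; biases are never penalized. The
mean squared error uses the $1/p$ normalization (per sample, summed over
features).

Two representational choices deserve comment:

* **Hidden activation.** The KL penalty requires mean activations in
  $(0,1)$, so hidden units are logistic sigmoids.
* **Decoder output.** Connectivity features are correlations in $[-1,1]$,
  which a sigmoid output cannot reproduce; the decoder is therefore
  *linear* by default. A `decoder_activation = "sigmoid"` switch restores
  the symmetric form for inputs that live in $(0,1)$ (e.g. with
  `feature_scaling = "unit_interval"`).

### Initialization

Parameters are drawn i.i.d. from a symmetric uniform distribution inside
$[-1, 1]$, in the fixed order $W_1, b_1, W_2, b_2$, from one seeded
generator per training call. The half-range is
$\min\!\big(1, \sqrt{6/(n+k+1)}\big)$, the classic fan-scaled (Glorot)
width. The scaling matters: at $n = 4005$ a literal unit range puts every
hidden pre-activation tens of units into the sigmoid tails, the
reconstruction gradient all but vanishes, and the optimizer then serves
only the KL term — every hidden unit collapses to the constant activation
$\rho$ and the learned representation is degenerate. We observed exactly
this collapse before adopting the scaled range; the scaled draw is still
uniform and still inside $[-1,1]$.

### Optimizer

All training stages — each autoencoder, the softmax head, and joint
fine-tuning — use Møller's scaled conjugate gradient (SCG), a batch
method with no line search and no learning rate, implemented from the
published algorithm (initial $\sigma = 10^{-4}$, initial scale
$\lambda = 10^{-6}$, comparison-parameter update as published). One
"epoch" is one SCG iteration. Training stops at the first of: cost
$\le$ `cost_goal` (default $10^{-5}$), gradient infinity-norm
$< 10^{-8}$ (prevents spinning at flat optima), or `max_epochs`. A
fixed-step gradient-descent fallback (`gd_minimize`, step 0.01) is
provided because fine-tuning is sometimes described with a
back-propagation learning rate of 0.01; SCG is the default everywhere and
the two never mix in one run.

### Stacking, transfer, and the two classifiers

`train_ssae()` builds an $L$-layer stacked sparse autoencoder greedily:
stage $l$ trains on the hidden activations of stages $1..l{-}1$ and keeps
only the encoding half. Offline learning is purely unsupervised — the
function accepts a feature matrix only, so target labels *cannot* leak in
— and the offline corpus must be disjoint from the target cohort by
subject id (the pipeline refuses overlap).

Two classifiers share one architecture and one set of hyperparameters:

* **DTL-NN** — `transfer_init()` copies the offline prototype, a softmax
  head (with intercepts, `softmax_intercept = TRUE`) is trained on the
  extracted features, and the whole network is fine-tuned jointly.
* **DNN baseline** — identical, except its SSAE is greedily pretrained on
  the target training folds themselves. Any performance difference is
  attributable to the pretraining corpus, i.e. to transfer.

The head minimizes the both-terms binary cross-entropy
$-\frac1m\sum_i\sum_j [y_{ij}\ln h_{ij} + (1-y_{ij})\ln(1-h_{ij})]$ with
predictions inside the logarithms (a logarithm of a hard 0/1 label is
undefined) and probabilities clamped to $[10^{-12}, 1-10^{-12}]$.
Fine-tuning optimizes this objective over the fully flattened parameter
vector with *no* L2 or sparsity penalties; penalties act only during
unsupervised pretraining. For two classes the softmax head is equivalent
to a single-logit sigmoid up to parameterization; the package uses the
full softmax and the equivalence is asserted in the tests. A predicted
probability of exactly 0.5 is assigned to the positive (disease) class.

## Site harmonization

Multi-site cohorts carry site- and demographics-linked feature shifts.
`site_bias_correct()` removes them per feature in two steps: (1) an
ordinary-least-squares fit of the feature on site, age, sex and
handedness (categoricals dummy-coded; reference level = first level
alphabetically, logged per run), after which the feature is replaced by
intercept + residual; (2) a site-mean adjustment subtracting each site's
departure from the grand mean over subjects ("mean value across all
sites" is read as the subject-level grand mean). Missing covariates are
imputed first — categorical by the cohort mode, numeric by the cohort
mean — with a logged count; IQ is not a correction covariate. Aliased
design columns (e.g. a single-sex cohort) are dropped with a warning
rather than failing the run. The model is fit on the union of offline and
target subjects by default, which mirrors how site-level correction is
described for the reference workflow; `fit_on = "train_only"` exists for
leakage-sensitive analyses.

## Evaluation and saliency

`cross_validate()` uses stratified $k$-fold splits (default $k = 5$;
per-class fold counts differ by at most one) and computes accuracy,
sensitivity, specificity and AUC on the *concatenation* of all held-out
folds, never as per-fold averages. AUC is the midrank (tie = ½)
probability that a positive outscores a negative; the test suite checks
it against exhaustive pair counting. Model comparisons across sites use
the classical paired t-test.

Discriminative connections are ranked by weight-product saliency: the
chained product $W^{(L)}\cdots W^{(1)}$ approximates
$\partial y / \partial \mathrm{FC}_{ij}$, and feature $j$'s score is the
sum of absolute product entries over top-layer units. Deliberately, the
product uses SSAE weights only — no activation derivatives and, by
default, no softmax coefficients (`include_head = TRUE` is available for
sensitivity analyses). Scores are computed per CV fold and *summed*
across folds ("accumulating the ranking weights" is read as accumulating
the weights that induce the ranking, not rank positions); ties rank by
ascending edge index. For a purely linear network the scores equal exact
Jacobian column norms, which the tests verify.

## Synthetic cohorts

`simulate_cohort()` generates everything the pipeline needs without any
imaging data. On the Fisher-z scale, a healthy edge value is

$$z = \mu + \Lambda u + \text{site} + \text{covariates} + \varepsilon,$$

with a per-edge baseline $\mu \sim N(0.25, 0.2)$, a shared low-rank
latent factor structure $\Lambda u$ (default 10 factors, total latent sd
0.4 per edge) that gives offline learning something transferable, site
offsets ($\mathrm{sd} = 0.1$), small age/sex/handedness effects
(0.01 per year, 0.1, 0.05), and independent noise
($\mathrm{sd} = 0.25$). Disease subjects are shifted by `effect_size`
(default 0.6) on a planted set of 10 random edges, and $r = \tanh(z)$
maps everything back to valid correlations — additivity on the z scale
never produces $|r| \ge 1$. Handedness is dropped at 5% to exercise
imputation. Offline and target subjects use disjoint id namespaces and
sites.

These defaults are meant to emulate the statistical regime of a
multi-site autism cohort: a per-edge standardized effect of
$0.6/\sqrt{0.25^2+0.4^2} \approx 1.3$ on 10 of 4,005 edges. The noise
level is deliberately set so that classifiers trained on a few dozen
subjects land in the 60–75%-accuracy band that published site-level
benchmarks occupy: with substantially heavier edge noise the
30-training-subject regime becomes information-theoretically
unlearnable for *any* method (we verified that a linear SVM comparator
drops to chance well before the planted-direction oracle does), and a
validation scenario in which nothing can learn validates nothing. What
the generator
does *not* emulate: realistic network topology (small-world structure,
community organization), hemodynamics, heavy-tailed motion artifacts, or
site differences in covariance structure (site effects are additive
shifts only). Passing tests therefore demonstrate that the machinery
recovers planted structure under the model's own assumptions, not
clinical performance on real rs-fMRI.

## Desk-scale transfer experiment

`run_transfer_experiment()` is the package's end-to-end validation: per
repetition it simulates a cohort, harmonizes it, trains the offline
prototype on ~400 healthy subjects from 8 non-target sites, and evaluates
DTL-NN and DNN by 5-fold CV on one small target site (19 + 19 subjects,
about 30 training subjects per fold) with identical folds, accumulating
DTL-NN saliency across folds. The shipped problem size for this
experiment is a 4005–15–15–15–2 network trained for up to 60 SCG
iterations per stage — wide enough to hold the 10-factor latent structure
plus planted signal, small enough that 20 repetitions run on a single
CPU in minutes. The per-site presets (`load_preset()`) retain the full
published configurations (widths 30–100, 400–800 epochs) for real-data
use.

## Numerical choices and degenerate inputs

* KL terms clamp mean activations to $[10^{-12}, 1-10^{-12}]$ (with a
  warning at the user-facing `kl_sparsity()`); cross-entropy clamps
  probabilities identically.
* Softmax subtracts the row maximum before exponentiation.
* `scg_minimize` aborts with the iteration number on non-finite
  objectives or gradients; non-finite inputs at the start are an
  immediate error.
* Zero-variance ROIs produce zero correlations with a warning;
  time-series containers require $T \ge 3$.
* `vectorize_fc` rejects asymmetry beyond $10^{-8}$;
  `simulate_timeseries` repairs non-positive-definite targets by
  eigenvalue clipping, with a warning.
* Stratified folds refuse classes smaller than $k$; the paired t-test
  refuses zero-variance differences.
* Model files are JSON with 17 significant digits, which round-trips
  IEEE doubles bit-exactly (verified in the tests).

### What the desk-scale experiment shows — and what it cannot

Across repeated 20-repetition runs the transfer network's mean
cross-validated accuracy exceeds the baseline's by roughly two
percentage points, a small margin against a per-repetition paired
difference spread of nine to eleven points: the direction is
consistently positive, but a 20-repetition one-sided paired test does
not reach significance at $\alpha = 0.05$. This is not an accident of
tuning; it follows from spiked-covariance theory. A rank-$q$ latent
structure with realistic per-edge strength (latent sd 0.4 against noise
0.25 at $p = 4005$) has factor eigenvalues orders of magnitude above
the detection threshold at $n = 30$, so the baseline's target-only
pretraining recovers essentially the same representation as the
offline prototype trained on 400 subjects, and the initialization
advantage that transfer provides is necessarily thin. A regime where
30 subjects cannot see the structure but 400 can would require either
implausibly faint factors or thousands of them. Real connectomes offer
what this linear-Gaussian generator cannot: many weak, nonlinearly
expressed, partially site-specific components — plausibly the regime
in which transfer initialization pays off more decisively. The
experiment's repetition-level results (both models' metrics, their
paired comparison, and the saliency overlap with the planted edges)
are returned by `run_transfer_experiment()` so users can judge the
margin directly.

## Known limitations

* The saliency product ignores activation nonlinearities; it is a
  first-order, fold-accumulated screen, not a calibrated effect size.
* Harmonization assumes additive confounds; scanner differences that
  alter covariance structure are out of scope.
* The generator's latent model is linear-Gaussian; conclusions about
  real rs-fMRI transfer must come from real corpora.
* Offline hyperparameters are shared across all stacked layers (per-layer
  overrides are a config edit away, but the shipped presets use one value
  per site, matching how the configurations are published).
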