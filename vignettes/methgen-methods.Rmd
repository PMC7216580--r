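---
title: "Conditional generative simulation of methylation beta values: models and methods"
author: "methgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional generative simulation of methylation beta values: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methgen)
```

## The problem

Public collections of cancer methylomes are large in aggregate but thin for
many individual cancer types, which limits studies that need many samples of
one specific type. `methgen` addresses this by learning the joint
distribution of Illumina 450K-style beta values and a categorical condition
(cancer type), and then sampling new methylome profiles for a *requested*
condition. A beta value is the fraction of methylated signal at a CpG site,
bounded in $[0, 1]$; the data are a samples $\times$ CpGs matrix $x$ with a
per-sample condition label $y$.

Two generators are provided:

* the **CVAE generator** — a conditional variational autoencoder, the
  package's core model; and
* the **beta benchmark** — an independent per-(CpG, condition)
  $\mathrm{Beta}(\alpha, \beta)$ model, the natural parametric baseline for
  bounded methylation values.

## The conditional variational autoencoder

A VAE posits latent variables $z$ with prior $p_\theta(z)$ and a decoder
$p_\theta(x \mid z)$; an encoder $q_\phi(z \mid x)$ approximates the
intractable posterior. Training maximizes the variational lower bound
$$\mathbb{E}_{q_\phi(z \mid x)}[\log p_\theta(x \mid z)]
  - \mathrm{KL}\!\left[q_\phi(z \mid x)\,\|\,p_\theta(z)\right].$$
The conditional variant conditions both networks on the label, giving
$$\mathcal{L} = \mathbb{E}_{q_\phi(z \mid x, y)}[\log p_\theta(x \mid z, y)]
  - \mathrm{KL}\!\left[q_\phi(z \mid x, y)\,\|\,p_\theta(z \mid y)\right],$$
so that after training, sampling $z \sim N(0, I)$ and decoding with a chosen
$y$ yields new data of that condition.

Concretely in `train_cvae()`:

* the posterior is a diagonal Gaussian: the encoder maps $(x \oplus y)$
  (one-hot $y$ concatenated to $x$) to $(\mu, \log\sigma^2)$;
* sampling uses the reparameterization $z = \mu + \sigma \odot \varepsilon$,
  $\varepsilon \sim N(0, I)$, so gradients flow through the draw;
* the KL term has the closed form
  $-\tfrac12\sum_d (1 + \log\sigma_d^2 - \mu_d^2 - \sigma_d^2)$
  (`kl_gaussian_vs_standard_normal()`, verified against numerical
  integration in the test suite);
* the reconstruction term is elementwise binary cross-entropy summed over
  CpGs. Beta values live in $[0,1]$, so treating them as Bernoulli
  probabilities against a sigmoid output is the natural likelihood; a
  squared-error alternative is available via
  `cvae_config(reconstruction_loss = "mse")`;
* optimization is minibatch Adam.

### Design choices that were genuinely open

The architecture below follows the reference design (hidden widths 500/250,
125 latent variables, ELU and tanh activations, Adam at learning rate 1e-3
for 10,000 epochs); several details are not pinned down by that description
and were fixed as follows.

* **Prior.** The conditional prior $p_\theta(z \mid y)$ is simplified to the
  standard normal $N(0, I)$, independent of $y$ — the conventional CVAE
  simplification; condition information enters through the decoder input
  instead.
* **Conditioning mechanism.** One-hot concatenation at both the encoder
  input ($x \oplus y$) and the decoder input ($z \oplus y$) — the canonical
  CVAE realization.
* **Activation placement.** ELU on the first hidden layer and tanh on the
  second, mirrored in the decoder; the output layer is a sigmoid so
  generated values are guaranteed to lie in $(0, 1)$. The plan is
  configurable (`cvae_config(activations = ...)`).
* **One model per chunk.** Preprocessing divides the CpGs into chunks
  (default 10,000); one independent CVAE is trained per chunk and generated
  chunks are concatenated. Nothing in the chunked training scheme requires
  cross-chunk parameter sharing, and independence is the simplest consistent
  choice. The cost is that long-range correlation *between* chunks is not
  modeled.
* **Batch size 100 and KL weight 1** (no annealing): unspecified in the
  reference description; plain defaults were fixed once.
* **Initialization.** Fan-in-scaled Gaussian weights under the configured
  seed; all RNG use (init, shuffling, $\varepsilon$) derives from
  `config$seed`, which is what makes training bit-reproducible.
* **Model state.** `save_state()` writes a single versioned container file
  (RDS); a round trip reproduces generation bit-for-bit. A single file was
  preferred over a directory layout because the state is one self-contained
  R object.

The implementation is a direct hand-written feed-forward network
(forward pass, backpropagation, Adam) on base matrix operations. At the
scale this package targets per chunk, BLAS-backed matrix products are fast,
and owning the training loop keeps every source of randomness seeded and
auditable.

## The beta benchmark

For each (CpG, condition) cell, `fit_table()` estimates
$\mathrm{Beta}(\alpha, \beta)$ by the **method of moments**: with clipped
sample mean $m$ and variance $v$,
$$c = \frac{m(1-m)}{v} - 1,\qquad \hat\alpha = mc,\qquad \hat\beta = (1-m)c.$$
The fitted distribution's analytic mean and variance reproduce the sample
moments exactly, which gives a sharp correctness oracle. Method of moments
was chosen over maximum likelihood because it is closed-form (the table has
one cell per CpG per condition — millions at 450K scale) and exactly
testable; values are clipped to $[10^{-6}, 1-10^{-6}]$ first because beta
moments degenerate at exact 0/1, which real array exports contain.

Cells that cannot be fitted — fewer than `min_n = 3` observations, zero
variance, or $v \ge m(1-m)$ (moment-infeasible) — receive a mean-preserving
surrogate $\mathrm{Beta}(m\kappa, (1-m)\kappa)$ with $\kappa = 1000$ and are
flagged `fallback` in the table. `sample_benchmark()` draws each cell
independently; the benchmark therefore carries no correlation between CpGs
by construction.

## Preprocessing

`preprocess_pipeline()` applies four steps, in order, to control the bias
that concentrated missingness would introduce:

1. **Drop all-missing CpGs** — a column with no observation at all.
2. **Chunk** the CpGs into consecutive blocks (default 10,000). Chunking is
   what lets a sample that is missing only in one region still contribute
   to every other chunk.
3. **Remove outlier samples per chunk** by the IQR rule applied to
   per-sample missing-value *counts*: counts above the upper Tukey fence
   $Q_3 + 1.5\,\mathrm{IQR}$ are discarded. The rule is **one-sided** —
   having few missing values is not a defect — and quantiles use the
   standard type-7 linear interpolation (the `quantile()` default). Both
   conventions had to be fixed; the whisker (1.5) is configurable.
4. **Impute** remaining missing entries with the per-CpG median across all
   retained samples of the chunk. Imputation is *not* stratified by
   condition (a stratified variant would be easy to add, but the global
   median is the simplest defensible reading and is what the audit report
   records).

The pipeline is idempotent, never alters an observed value, and records
every removal and imputation in a `preprocess_report`. A degenerate corner
is guarded explicitly: if outlier removal leaves a CpG with no observations
inside one chunk, that CpG is dropped from the chunk and recorded, rather
than imputed from nothing.

## The synthetic ground-truth generator

`generate_ground_truth()` produces the fixture data every module is tested
on: per-(CpG, condition) beta-distributed values with known parameters.
Generating parameters are drawn by choosing a mean and a concentration
$c = \alpha + \beta$ and setting $\alpha = \text{mean}\cdot c$,
$\beta = (1-\text{mean})\cdot c$, which separates location from dispersion
and makes the mean structure directly controllable:

* at an **informative** CpG (fraction `frac_informative`, default 0.5) the
  $K$ conditions receive $K$ equally spaced means with spacing
  `mean_separation` (default 0.3), randomly permuted across conditions, so
  the spacing is the *minimum* pairwise mean difference; feasibility
  requires `mean_separation * (K - 1)` $\le 0.9$ since means are kept in
  $[0.05, 0.95]$;
* at an uninformative CpG all conditions share one parameter set;
* concentrations are drawn from `concentration_range` (default 20–60,
  i.e. within-condition standard deviations of roughly 0.05–0.11, typical
  of 450K beta values);
* `inject_missing()` adds missing-completely-at-random entries plus
  designated high-missingness outlier samples — exactly the structure the
  preprocessing targets — and returns the mask for oracle tests.

What the generator does **not** emulate: co-methylation blocks and genomic
spacing, array probe-type chemistry effects, batch effects, and boundary
inflation at exact 0/1. Tests passing on these fixtures therefore
demonstrate that the algorithms do what they claim under the assumed
beta-mixture structure, not that the CVAE will match every property of real
TCGA data.

## Evaluation protocol

`compare_generators()` implements the classification-based protocol: per
repetition it (1) splits the data 70/30 stratified by condition, (2) fits
both generators on the 70% partition, (3) trains multi-class classifiers —
decision tree, naive Bayes, random forest, k-nearest neighbours, SVM — on
the 30% partition, (4) generates `n_generated_per_condition` samples per
condition per generator (default 100), and (5) classifies them; a generated
sample counts as correct iff it is predicted as its intended condition.
Defaults are 100 generated samples per condition and 10 repetitions.
Both the split and the generation seeds are re-drawn each repetition (the
alternative — pinning one of them — is a flag away via the per-repetition
seeds recorded in `settings`).

Classifier hyperparameters are library defaults with fixed seeds, recorded
in the report, to keep the comparison reproducible rather than tuned. Two
scoring details are worth noting:

* **SVM** is a set of one-vs-rest binary machines; their decision values
  are the per-condition scores and the multiclass prediction is their
  argmax. (The orientation of `e1071` decision values follows order of
  appearance in the training data; the package normalizes it so positive
  always means the target condition.)
* **KNN** per-condition scores are the k-nearest-neighbour vote fractions,
  computed explicitly so that scores exist for AUC and ties break
  deterministically (first label in vocabulary order) — an off-the-shelf
  KNN that breaks ties at random would violate the package's
  reproducibility contract.

One-vs-rest AUC is the rank-based Mann–Whitney statistic with midrank tie
handling, tested against an exhaustive pair-counting oracle and against an
established ROC implementation.

`embed_tsne()` offers a joint three-dimensional t-SNE embedding of real and
generated samples as a visual diagnostic. It is an exact (non-Barnes-Hut)
t-SNE with standard settings (PCA compression to 50 components, perplexity
calibration by bisection, early exaggeration, momentum), implemented in the
package and intended for the few hundred samples a diagnostic needs, not
for embedding whole cohorts.

## Numerical choices and degenerate inputs

* Cross-entropy inputs are clipped to $[10^{-6}, 1-10^{-6}]$; training uses
  the logit form of the loss, which is overflow-safe.
* Decoder outputs are clamped to $[10^{-12}, 1-10^{-12}]$ so "strictly
  inside $(0,1)$" holds even where a sigmoid underflows in double
  precision.
* I/O stores values with 17 significant digits (lossless for doubles) and
  never clips: range violations beyond $10^{-9}$ are errors, sub-tolerance
  overshoot is clamped to the boundary.
* All derived seeds are kept inside the 32-bit integer range.
* Degenerate inputs (empty matrices, single chunk remainder, zero generated
  samples, all-missing columns, conditions absent from a chunk) have
  defined behavior and tests.

## Problem sizes used by the test suite

The packaged checks run the full stack at reduced, fixed scale, chosen once
as the smallest sizes at which every property is comfortably identifiable:
the reference fixture is 4 conditions $\times$ 200 CpGs $\times$ 150
samples/condition with mean separation 0.3, and the reduced CVAE is
64/32 hidden units, 16 latent variables, batch 50, 500 epochs. The
benchmark-recovery check uses 500 samples per condition; the null-control
check uses a fixture whose conditions share identical generating
parameters, where classification accuracy must be statistically
indistinguishable from chance. `scripts/acceptance.R` recomputes all of
these quantities from scratch under a caller-supplied seed.

## Known limitations

* Chunks are modeled independently: correlation between CpGs in different
  chunks is absent from generated data (within-chunk correlation is
  captured by the CVAE's latent space; the beta benchmark has none at all).
* The 10,000-epoch default configuration is the reference setting for
  cohort-scale data; it is far more than the reduced fixtures need and
  should be scaled with the data at hand.
* Median imputation is global per chunk, not per condition.
* The evaluation protocol measures whether generated samples are
  *recognizable* as their condition — a necessary, not sufficient,
  criterion for distributional fidelity; the t-SNE diagnostic and the
  benchmark's moment identities probe complementary aspects.
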