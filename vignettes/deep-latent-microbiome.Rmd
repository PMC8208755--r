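---
title: "Predicting microbiome composition through a deep latent space"
author: "LatentMicrobiome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbiome composition through a deep latent space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LatentMicrobiome)
```

## The problem

A 16S rRNA survey of a microbial community yields a *composition*: a
vector of relative abundances over hundreds of operational taxonomic
units (OTUs). Sequencing is expensive and not always available, while
environmental covariates — temperature, precipitation, plant age, host
genotype — are cheap to measure. LatentMicrobiome models the mapping
*environment → composition* so that the full community profile of, say,
a maize rhizosphere sample can be predicted from a handful of such
covariates, and extrapolated to hypothetical conditions such as climate
change scenarios.

Predicting hundreds of correlated, compositional outputs directly is
hard. The package's central idea is to first compress the composition
into a small *deep latent space* with an autoencoder, and then predict
that latent code — roughly ten numbers instead of hundreds — from the
environmental features, decoding it back to a full composition.

## Model architectures

Three network modules are combined into the architectures:

* an **OTU encoder** mapping a composition $x \in \Delta^{p-1}$ to a
  latent code $z \in \mathbb{R}^d$;
* an **environmental encoder** mapping encoded features $v$ to a latent
  code;
* a **decoder** mapping any latent code back to a composition
  $\hat{x}$.

The *OTU autoencoder* (`trainOtuAutoencoder`) is the classical
encoder–decoder pair trained to minimize a reconstruction loss
$L(\hat x, x)$. The *combined (heterogeneous) autoencoder*
(`trainCombinedAutoencoder`) trains both encoders against one shared
decoder with the loss

$$ L(\mathrm{dec}(z_{\mathrm{otu}}), x) + L(\mathrm{dec}(z_{\mathrm{env}}), x)
   + w \, \lVert z_{\mathrm{otu}} - z_{\mathrm{env}} \rVert^2 / (nd), $$

so that the two latent spaces are forced toward each other while both
remain decodable. Both reconstruction paths propagate gradients into the
shared decoder; this is what makes the final assembly coherent, since at
prediction time only the environmental path is available. The alignment
weight $w$ (`alignWeight`) defaults to 1.

The deployable *prediction model* (`assemblePredictionModel`) is
environment → latent → frozen decoder → composition. The latent stage is
either the trained environmental encoder (`combined` mode) or a
dedicated regressor trained by mean squared error on the frozen OTU
encoder's codes (`otu_latent` mode). No end-to-end fine-tuning is done
by default: the decoder is the transferable, frozen asset.

## Compositional scales and losses

Counts are normalized per sample by total-sum scaling (TSS), optionally
followed by the centered log-ratio transform (CLR) with a pseudocount
(default 1) added to counts beforehand — the standard simple choice for
the zeros that dominate microbiome data, and recorded inside every
trained model (`NormalizationState`) so outputs can always be mapped
back to relative abundances by `inverseToRelative` (clip-and-reclose for
TSS, softmax for CLR).

Three training losses are available: MSE on either scale, and
crossentropy or Bray–Curtis dissimilarity
($\sum_i |u_i - v_i| / \sum_i (u_i + v_i)$), which act on simplex-valued
predictions and therefore require the TSS pathway with a softmax output
head; requesting them under CLR is rejected as a configuration error.
Crossentropy uses $\varepsilon = 10^{-8}$ inside the logarithm for
stability.

Evaluation always happens on the TSS scale after `inverseToRelative`, so
models trained under different normalizations are directly comparable.
The metric panel (`evaluateComposition`) reports mean Pearson
correlation, mean per-sample Bray–Curtis, MAE/MSE/MAPE (MAPE over
positive entries only) and per-taxon root relative squared error (RRSE).

**Pearson orientation.** Correlation can be computed per sample (across
taxa) or per taxon (across samples). The default is per-sample: a mean
predictor is constant per taxon, so its per-taxon correlation does not
exist — and a finite published correlation for such a predictor is only
consistent with the per-sample reading. Both orientations are
implemented; the per-taxon one raises an error when every pair is
constant rather than silently returning 0.

**RRSE.** For taxon $j$,
$\sqrt{\sum_s (\hat x_{js} - x_{js})^2 / \sum_s (x_{js} - \bar x_j)^2}$:
1.0 means no better than predicting the taxon's mean, which makes it
scale-independent and usable to rank best-predicted taxa
(`rankBestPredicted`, ascending RRSE, ties broken by taxon id). The
denominator uses the evaluation-set mean by default and can be switched
to training-set means.

## Tunable parameters

`architectureConfig()` carries the architecture and training settings.
The declared grid (`enumerateGrid`, 1296 raw cells before removing
invalid loss–normalization pairs) spans latent sizes {10, 50, 100},
hidden layers {(512, 256), (256), none}, encoder/decoder activations
{tanh, relu, sigmoid}, latent activations {tanh, sigmoid},
normalizations {TSS, TSS+CLR}, losses {MSE, crossentropy, Bray–Curtis},
learning rates {0.01, 0.001} and batch sizes {64, 128}. Defaults: latent
10, hidden (256), tanh, TSS + Bray–Curtis, learning rate 0.001, batch 64
— the small-latent reference configuration. The optimizer is Adam;
training runs up to 100 epochs with early stopping at patience 10 on
validation loss, restoring the best weights.

One deliberate exception: the environment-to-latent predictor gets a
longer schedule (at least 300 epochs, patience 30). It regresses only
~10 outputs, so its epochs are two orders of magnitude cheaper than
autoencoder epochs, and its validation loss is too noisy early on for
patience-10 stopping to be reliable.

`gridSearch` evaluates each configuration by k-fold cross-validation of
the *assembled* prediction model and ranks by descending mean CV Pearson
with ties broken by ascending Bray–Curtis — an explicit ordering of the
dual selection criterion. Within each fold, an internal seeded 90/10
split of the fit samples drives early stopping, so fold-validation
samples never influence training.

## The synthetic-data generator

Real rhizosphere studies cannot be bundled, so `generateSyntheticDataset`
emulates the statistical structure the method assumes: five
environmental features (age 0–20 weeks, temperature 50–90 °F, rain 0–5
inches, a 4-level line and a 6-level variety) drawn uniformly; true
latent factors $z = \tanh(\mathrm{affine}(v)) + \epsilon$ (noise sd
0.1); per-taxon logits as a linear loading of $z$ plus intercepts, with
30% of taxa given strongly negative intercepts to reproduce microbiome
sparsity; proportions by softmax; and counts by a per-sample multinomial
draw at depth 10 000. The reference fixture is 2000 samples × 200 taxa
over 12 phyla with true latent dimension 5 (seed 7). The truth bundle
(coefficients, latent factors, proportions) is returned so tests can use
the generator itself as an oracle. `perturbForTransfer` derives a small
dataset whose features are *different* nonlinear functions of the same
latent factors (stand-ins for soil pH, nitrogen and carbon), emulating a
small study with disjoint metadata.

What the generator does *not* emulate: phylogenetic covariance among
taxa, overdispersion beyond multinomial noise, batch effects,
spatial/temporal autocorrelation, and the heavy-tailed abundance
distributions of real surveys. Tests passing on this fixture show the
machinery is correct and that the architecture recovers a recoverable
signal; they do not certify performance on any real dataset.

## Numerical choices

* Z-scoring of numeric features uses the population (n) standard
  deviation; categorical vocabularies are sorted for deterministic
  column order; unseen categories encode as an all-zero block with a
  warning; zero-variance features encode as constant 0.
* All randomness (initialization, shuffling, splits) flows from explicit
  integer seeds; identical seeds give bit-identical results.
* Model bundles persist as directories of plain-text files with
  `%.17g`-formatted parameters, which round-trips IEEE doubles exactly:
  a reloaded model predicts bit-identically.
* A rank-deficient linear-baseline design (e.g. intercept plus full
  one-hot blocks) falls back to the least-norm (pseudoinverse) solution
  with a warning.
* An all-zero sample is a hard error at TSS time (`zero-depth sample`);
  degenerate all-zero model outputs re-close to zero rather than NaN.
* Softmax evaluations subtract the row maximum before exponentiation.

## Transfer learning

`transferFit` re-uses a trained decoder and latent geometry for a small
dataset: the small study's compositions are pushed through the source
OTU encoder to obtain latent targets, a fresh encoding schema is fitted
on its (possibly entirely different) features, and only a new
environment-to-latent predictor is trained. The decoder is frozen —
`parameterDigest` is bit-identical before and after. Taxa must match the
decoder's outputs exactly by id; datasets annotated incompatibly are
first aggregated to a shared rank (`aggregateTaxa`) on *both* sides and
transferred at that rank through a source model trained at that rank.
This package deliberately supports only the aggregate-then-match route;
predicting full-resolution outputs and aggregating afterwards is left to
the caller, since cross-study identifier reconciliation beyond exact
matching is out of scope.

## Scenario prediction

`scenarioPredict` overrides named features (e.g. temperature 86 °F, rain
0 in for a "hot and dry" condition) for every sample and tabulates the
predicted compositions long-format, optionally aggregated to a rank.
Values outside the training range are allowed with a logged
extrapolation warning — near-boundary scenarios are the point of the
exercise — but no causal validity is claimed for extrapolated
predictions. Units are whatever the schema recorded (the bundled
generator uses °F, inches, weeks); conversions are the caller's
responsibility.

## Problem sizes used in the test suite

The suite exercises the full reference fixture (2000 × 200) for the
acceptance-style properties — reconstruction fidelity, model-family
ordering, rank-aggregation monotonicity, transfer, grid selection — and
a 300 × 40 dataset for per-module unit tests. These sizes were chosen so
the whole suite trains a dozen networks in a few minutes on one CPU
while remaining far above the regime where the properties are trivially
noisy.

## Known limitations

* The network engine is a compact dense-layer implementation (Adam,
  early stopping, analytic gradients) sized for hundreds of taxa and
  thousands of samples on CPU; it is not a general deep-learning
  framework and has no GPU path.
* Grid search retrains the autoencoder for every configuration × fold;
  the full 864-cell declared grid is meant for batch runs, not
  interactive use.
* Stratified splitting is not implemented; splits are uniform random
  permutations under a seed.
* MAPE excludes zero-actual entries rather than offsetting them, and is
  reported as a fraction.
* The per-epoch alignment term of the combined autoencoder fluctuates
  with minibatch noise at convergence; it is far below its untrained
  value but not strictly monotone epoch-to-epoch.
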