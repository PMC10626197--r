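---
title: "Sequential model optimization for drug-combination synergy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential model optimization for drug-combination synergy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synergyloop)
```

This vignette is the package's account of its science: the synergy score and
its pooling, the regression model, uncertainty estimation, the acquisition
loop, the synthetic landscape generator, and the numerical choices made where
the design was genuinely open. Code chunks are illustrative and not executed
at build time; the test suite and `scripts/acceptance.R` compute every
empirical claim made here.

## 1. The Bliss score and its pooling

Under Bliss independence, two non-interacting drugs kill multiplicatively:
the expected combined viability is $V(c_1)\,V(c_2)$. Writing inhibition
$I = 1 - V$, the elementwise excess over that null,

$$ s(c_1,c_2) \;=\; I(c_1,c_2) - I(c_1) - I(c_2) + I(c_1)\,I(c_2), $$

is positive where the combination kills more than independence predicts.
`blissExcessMatrix()` computes it in fractional units and reports ×100.

A dose–response matrix must be collapsed to one label per pair. We pool by
the **maximum** excess over the nonzero-dose grid (`poolSynergy(..., "max")`).
Rationale: laboratories choose different dose windows, and a pair typically
synergizes in a specific dose interval, so the arithmetic mean is highly
sensitive to the window while the maximum is comparatively stable. Mean
pooling is provided for comparability with studies that use it.

Three concrete conventions, fixed once:

* **Replicates** are averaged on the inhibition scale *before* the excess is
  computed (`aggregateReplicates = "before"`); scoring each replicate and
  averaging afterwards is exposed as `"after"` since published pipelines are
  not always explicit about the order and the two differ under noise (the
  excess is bilinear in the single agents, so they coincide exactly only on
  noiseless data).
* **Zero-dose margins are excluded from pooling.** The excess is defined for
  two administered doses; the margins are identically zero under exact
  normalization and carry only noise in practice.
* **Per-triplet noise** (`estimateReplicateNoise()`) uses the sample (n−1)
  standard deviation: replicate counts are small and the unbiased-variance
  convention is the defensible default. Note the estimator of the *sd* is
  still biased low for tiny n (about 8% at n = 4); the recovery tests hold
  at that replicate count.

Plate normalization follows the screening convention: per replicate, 0%
viability is anchored at the highest-concentration doxorubicin (total-kill)
well; per combination, 100% at the (0,0) DMSO control; values are capped
into [0, 100] and converted to fractional inhibition. Quality control drops
blocks with inhibition standard deviation ≤ 0.05, blocks smaller than 3×3,
and blocks whose mean inhibition falls outside (0.05, 0.95).

## 2. Drug features

Drugs are featurized as a concatenation of a circular (Morgan-style)
fingerprint and a one-hot identity block, with disabled blocks zero-filled so
model capacity is identical across feature-importance experiments. The
fingerprint (radius 2, 1024 bits by default) is computed in-package: atom
environments are hashed iteratively outward and folded into the bit vector.
It is deterministic and satisfies the usual similarity contracts; bit-level
identity with other toolkits' implementations is neither needed nor claimed,
since all similarity computations stay inside one consistent fingerprint
space.

The library-design step condenses a candidate collection to k representative
compounds by k-medoids over Tanimoto distance (1 − intersection/union), with
a seeded k-medoids++ initialization written in-package and PAM swap
refinement delegated to `cluster::pam`. PAM runs its swap phase to
convergence, so the fixed iteration cap contemplated during design is moot —
the objective can only improve on the initialization, which the tests
assert. An availability-replacement hook (`nearestAnalogue()`) swaps an
unavailable medoid for its most similar same-cluster member.

## 3. The regression model

`SynergyModel` is a permutation-invariant pairwise regressor:

1. **Encoder** — an MLP $E:\mathbb R^{l_D}\to\mathbb R^{k_D}$ (default one
   hidden layer of 1024, embedding 128) shared by both drugs.
2. **Combination** — a bilinear tensor $B \in \mathbb R^{k_D\times k_D\times k}$:
   $z_i = e_1^\top B_i\, e_2$. Each slice is stored unconstrained as $W_i$
   and evaluated as $(W_i + W_i^\top)/2$, which makes every forward pass
   exactly symmetric in the two drugs while keeping optimization
   unconstrained. $k$ (default 64) is tied to the first width of the
   combination head, as no separate value is singled out by the
   architecture search.
3. **Head** — an MLP $\mathbb R^k \to \mathbb R$ (default one hidden layer
   of 64).

**Cell-line conditioning** uses FiLM: per hidden layer, scale and shift
vectors $\gamma(c), \beta(c)$, linear in the cell features, applied after the
affine layer and before the nonlinearity. Both encoder and head are
conditioned (conditioning only one of them is a strict special case). FiLM
weights initialise at zero so that $\gamma \equiv 1, \beta \equiv 0$: an
unconditioned model and a freshly conditioned one agree exactly, which the
tests exploit.

Numerical choices:

* **Activation** ReLU; **optimizer** Adam with learning rate $10^{-4}$ and
  weight decay $10^{-4}$ as package defaults — values from within the
  searched grids, exposed in `synergyModelConfig()` because the selected
  values for these two knobs are not otherwise pinned down.
* **Target standardization.** Synergy labels live on a ×100 scale; training
  against z-scored targets (the affine transform is stored on the model and
  inverted at prediction) keeps the number of optimizer steps needed
  independent of the label units. A fine-tuned model keeps its pretraining
  transform so loaded weights stay aligned.
* **Early stopping** monitors validation MSE (20% internal split, re-drawn
  per fit from the fit's seed), patience 20 of at most 500 epochs, weights
  restored to the best checkpoint.
* All randomness (initialization, splits, shuffling) flows from one integer
  seed via named substreams, so every fit is exactly reproducible.

A concatenation-MLP baseline (`deepSynergyBaseline()`) is included: inputs
standardized then tanh-squashed, input dropout 0.2 and layer dropout 0.5,
prediction averaged over both drug orderings. Reference widths are
8182/4096; scale them down for small studies. Grids documented for
completeness but **not implemented** (off-the-shelf learners outside this
package's scope): gradient-boosted trees (depth {2,5,10,20}, min-split
{2,...,50}, learning rate {1e-4..1}, 100 trees) and linear SVM (tolerance
{1e-1..1e-6}, C {1e-4..10}).

## 4. Uncertainty

Two estimators of the predictive distribution's standard deviation:

* **Deep ensembles** (default; size 5 in silico, 36 for recommendations):
  members differ only in seed; $\hat\mu$ is the member mean and $\hat\sigma$
  the member *population* (n) standard deviation — the ensemble is the whole
  predictive sample, not a subsample of one.
* **Direct (DEUP-style) estimation**: a mean predictor trained with MSE
  (found more stable than a joint likelihood fit), then an uncertainty
  predictor of the same architecture — the architecture mirror is our
  choice, nothing deeper — trained on the *frozen* residuals with the
  Gaussian negative log-likelihood
  $\mathrm{NLL} = \tfrac12\log\hat\sigma^2 + (y-\hat\mu)^2/(2\hat\sigma^2)$.
  The head parameterizes $\log\hat\sigma^2$ for stability (the NLL diverges
  as $\sigma \to 0$), its output bias starts at the log marginal residual
  variance, and $\hat\sigma$ is floored at $10^{-3}$. Freezing the mean
  predictor first (rather than joint training) keeps the two estimation
  problems separable and reproducible.

## 5. Acquisition and the loop

Strategies over candidates $x$: brute force (seeded noise → random
selection), greedy $\hat\mu(x)$, pure exploration $\hat\sigma(x)$, and UCB
$\hat\mu(x) + \kappa\hat\sigma(x)$ with $\kappa = 1$ by default. Ranking
ties break on a seeded random key, so equal scores yield reproducible
batches.

Batch rules mirror the three screening regimes: drug-disjoint (each drug at
most once per batch — calibration), diversity-first (walk the ranking, admit
the first candidate that introduces a drug unseen so far; a candidate
qualifies if *at least one* of its drugs is new, the literal reading of the
rule), and per-drug caps (default 5 per batch, guarding chemical stock).
The cap counts within the current batch by default; a cumulative-history
mode is available since the alternative reading is defensible.

`runSmo()` starts from `initSize` (default 30) random candidates and then,
each round: re-splits the visible set 80/20 with a fresh per-round seed,
trains a fresh ensemble **from scratch** (retraining avoids overfitting
examples acquired early), scores the hidden pool, selects a batch, queries
the oracle, and augments. Failed oracle queries are logged and never retried
(live-lab realism; a retry would re-spend budget on a flaky well). Under
brute force no model is trained — the scores are noise by definition, which
keeps the random baseline cheap.

Fine-tuning for recommendation mode loads each pretrained model's weights
and continues training on the new data only (all weights free — no layer
freezing, the simplest defensible default), once per fine-tune seed: 3 × 12
= 36 members.

## 6. Evaluation harness

* **Splits**: default 70/20/10 over combinations; one-unseen-drug and
  two-unseen-drugs hold out 30% of drugs and split the seen–seen remainder
  80/20; shuffled-labels applies the default split after whole-row feature
  permutation (fingerprint and one-hot blocks move together — permuting them
  independently would leave identity information intact and defeat the
  ablation's purpose).
* **Metrics**: R², Spearman (average ranks on ties), and uncertainty-weighted
  explained variance with weights $w_i = 1/\hat\sigma_i$:
  $EV_w = 1 - \mathrm{Var}_w(y-\hat y)/\mathrm{Var}_w(y)$ with weighted
  means inside the variances. Only the weights are externally prescribed;
  this estimator form is our concrete choice and is isolated in one function
  so it can be swapped.
* **Enrichment**: reversed cumulative densities $P(S \ge s)$ and their ratio
  between a strategy's queries and random queries; 0/0 points are reported
  missing. The default "synergistic" threshold for summaries is a max-Bliss
  of 30, with 40 as the stricter alternative.
* **Noise bound**: corrupt the true synergies with $\mathcal N(0,\eta^2)$,
  let a hypothetical perfect regressor fit the corrupted values exactly, and
  score it against the truth; the average over simulations bounds what any
  model trained on observations at noise level $\eta$ can achieve.

## 7. The synthetic landscape generator

The generator defines the study conditions under which the package tests
itself; its defaults are fixed once:

* **Library**: drugs carry latent mechanisms (balanced assignment; 10
  mechanisms by default). Each mechanism has a deterministic base bit
  pattern (density 0.15 of 1024 bits); a drug's pseudo-fingerprint flips
  each bit with probability 0.05, so within-mechanism Tanimoto similarity
  (~0.6) well exceeds cross-mechanism similarity (~0.1) — the
  structure/mechanism correlation that fingerprint-driven generalization
  requires.
* **Landscape**: a few planted mechanism pairs (3 of 55 by default) carry
  large effects drawn from a location-scale exponential tail
  (40 + Exp(mean 15), spanning the 50–100 range where screened top scores
  live). The background is a mechanism-pair base effect
  $\mathcal N(0, 4)$ plus pair-level jitter $\mathcal N(0, 3)$. The
  mechanism-level component matters: with a purely i.i.d. background there
  is nothing for a model to learn outside the rare planted pairs, and no
  model-guided strategy can beat random sampling — real screens are
  mechanism-structured, and the generator reflects that. The resulting score
  distribution is concentrated near zero with a heavy positive tail
  (positive excess kurtosis whenever the lookup is non-empty).
* **Observation noise**: $\mathcal N(0, \eta^2)$ per replicate with
  $\eta = 5$ by default — a plausible replicate sd for max-pooled Bliss
  labels on the ×100 scale; simulated campaigns average 3 replicates,
  matching common screening practice.
* **Dose–response blocks**: 1:3 dilution series, 5 concentrations plus a
  zero dose (6×6 grids), four-parameter sigmoidal single agents with Hill
  slopes in [1, 2] and potency drawn relative to the grid span. A planted
  synergy $s > 0$ becomes a localized excess bump with Gaussian spatial
  decay around a seeded dose cell (synergy occurs in a specific dose
  window), with the peak placed where the independence surface leaves
  headroom so the noiseless max-pooled score equals $s$ exactly. A
  non-positive $s$ is planted as a *uniform* excess on potent single-agent
  backgrounds: a localized deficit can never lower the grid *maximum*, so
  antagonism is only max-pool-recoverable when every cell supports it; the
  potency and slope ranges guarantee exactly that for the background score
  range. The narrower slope range (not [0.5, 2]) is what keeps the low-dose
  corner flat enough to plant scores up to the mid-90s — the round-trip
  recovery guarantee took precedence over slope diversity.

What passing tests on this generator do **not** show about real data:
batch effects between studies, dose-window misspecification, activity
cliffs (structurally similar drugs with divergent effects), cell-line
heterogeneity beyond FiLM's reach, and assay artefacts are all absent.
Results on the generator are statements about the pipeline's mechanics and
statistics, not about biology.

## 8. Problem sizes used in the checks

The automated checks run simulations at deliberate desk scale: landscapes of
46 drugs (≈1,000 pairs, ~1% planted high synergies for the search
benchmark), models with a 64-unit encoder and 16-dimensional embeddings,
ensembles of 3, ten rounds of 30 queries, and 3–5 seeds per stochastic
claim. These sizes were chosen as the smallest at which the qualitative
phenomena of interest — enrichment of model-guided search over random,
the default > one-unseen > two-unseen generalization ordering, heteroscedastic
uncertainty recovery — are stable across seeds.

## 9. Known limitations

* Only Bliss scoring is implemented; highest-single-agent and dose-additivity
  (Loewe) models, and Hill-curve fitting, are out of scope.
* The fingerprint is a clean-room circular implementation; external
  fingerprint files from other toolkits should not be mixed with fingerprints
  computed here.
* Training is single-threaded dense linear algebra: configurations in the
  reference range (1024-unit encoder, 128-dim embeddings, 64 slices) train
  in minutes on thousands of records, not seconds.
* The SMO loop assumes a pointwise oracle with per-candidate failures;
  plate-layout design and laboratory integration are out of scope.
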