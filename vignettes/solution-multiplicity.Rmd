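---
title: "Solution multiplicity in two-group expression classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solution multiplicity in two-group expression classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Motivation

Classification studies on two-class expression data (a few thousand
continuous features, tens to low hundreds of samples) usually report a
single trained model and a single selected marker panel. Both are
under-determined: with so few samples relative to features, many different
models and many different small feature subsets achieve near-identical
held-out performance — the Rashomon effect. `multisol` makes that
multiplicity measurable in two complementary ways: at the *model* level, by
repeating randomized training on a fixed feature set and counting the
solutions above an accuracy cutoff; and at the *feature-subset* level, by
exhaustively scoring every triplet of the top-ranked features.

## The classifier

The workhorse is an extreme learning machine (ELM): a single-hidden-layer
feed-forward network whose input weights are random and *frozen*, so that
training reduces to a linear least-squares problem and every seeded fit is a
cheap, independent draw from the solution space.

Given training data $X \in \mathbb{R}^{m \times n}$ (features standardized
to train-set mean 0, SD 1; constant features get scale 1):

1. Draw $W \in \mathbb{R}^{h \times m}$ and $b \in \mathbb{R}^h$ i.i.d.
   uniform on $(-s, s)$ from the seeded generator.
2. Hidden activations $H = \sigma(WX + b)$ with $\sigma = \tanh$.
3. Readout: encode labels $y \in \{0,1\}^n$ (positive class = 1) and solve
   $\min_\beta \lVert [\,1\ H^\top]\beta - y \rVert_2$ by the minimum-norm
   SVD solution, discarding singular values below $10^{-10}$ relative to the
   largest. Rank-deficient $H$ is expected (not an error).
4. Predict positive iff the continuous score is $\ge 0.5$.

With $h \ge n$ and generic data $H$ has full row rank in the sample
dimension, so the network interpolates its training labels — the test suite
asserts this on seeded toys and verifies the readout against an independent
`MASS::ginv` pseudoinverse oracle.

**Parameter choices.** The reference implementation this design follows is
described only as an MLP-style random input layer without stated activation
or weight distribution, so we declare conventional substitutes — tanh units,
uniform $(-1, 1)$ weights — and record them in the run manifest; both are
config switches (`activation`, `weight_scale`). Standardizing features
before the projection makes `weight_scale = 1` meaningful across datasets of
different dynamic range. Hidden sizes default to the conventional screen
settings: 150 units for 20-feature inputs, 290 for all-feature inputs, and
150 for the (heavily over-parameterized) 3-feature triplet models, where the
hidden size is not prescribed.

A trained model is *represented* by its $h \times m$ input weight matrix.
Two models are compared by the elementwise difference matrix
$|W_1 - W_2|$; its maximum entry summarizes how different two equally
accurate solutions are, and anchors the white-to-red heatmap scale.

## The two screens

**Model screen** (`run_screen`). A fixed feature set — the 20 smallest-p
t-test features (`Top20Features`) or all features (`AllFeatures`) — and
`n_runs` seeded fits, run $i$ using seed `base_seed + i`. The census counts
runs with test accuracy **strictly greater** than the cutoff (0.8 for
difficult problems, 0.9 for easy ones) and reports the min/max accuracy
above it. Among tied-best runs, `best_pair` picks two at random under a
declared tiebreak seed and feeds `weight_difference`.

*Split policy.* The headline protocol is ambiguous about whether each of the
repeated fits re-splits the data. We default to one fixed stratified 70/30
split shared by all ELM runs — matching the phrasing that runs differ by
their randomly generated input weights — while `baseline_screen` defaults to
a fresh split per run, which is the only randomness available to
deterministic baselines. Both are config switches (`split_policy`), so
either reading can be reproduced.

*Baselines.* `baseline_screen` takes any classifier honoring a minimal
fit/predict contract. The package ships an ELM adapter (used by a test to
prove interface equivalence with `run_screen`), a logistic-regression
adapter over `stats::glm`, and a majority-class dummy as the chance-level
control. SVM and naive-Bayes baselines plug into the same contract when an
implementation is available in the user's library; re-implementing them is
out of scope here.

**Triplet screen** (`screen_triplets`). All $\binom{k}{3}$ subsets of the
top-$k$ (default 50 → 19,600) t-test features, each fitted as a 3-feature
ELM and scored for accuracy, precision and recall on a held-out set. Records
carry the rank triple $(x, y, z)$, $x \le y \le z$, and its mean. The census
here uses **metric ≥ cutoff** — deliberately non-strict, unlike the model
screen, because the two source protocols state the two inequalities
differently; both are honored as written and are configurable.
`best10` returns the ten best triplets per metric (ties broken by smaller
mean rank, then lexicographic ranks, for reproducibility) together with the
min/max of their mean ranks — the rank-dispersion statistic showing that
good triplets are not simply the top-3 ranked genes.

*One split or many?* We share a single seeded 80/20 stratified split across
all triplets: it makes the 19,600 metrics directly comparable and the census
meaningful as a count over a common test set. A per-triplet-split mode
(`shared_split = FALSE`, split seed = base seed + triplet index) is provided
for sensitivity analysis. The per-triplet fast path reuses the shared split,
the standardization, and the single $h \times 3$ hidden-layer draw; a test
pins it to the plain `fit_elm`/`evaluate_model` route so the optimization
can never drift from the public contract.

**t-test ranking.** The protocol says only "t-test"; we default to Welch
(unequal variances), the safer choice for expression data, with Student's
pooled test as a switch (`var_equal`), recorded in the manifest. Two-sided
p-values, no multiple-testing correction (ranking only). Ties in p are
broken by input feature order; a feature with zero variance in both classes
is assigned $t = 0, p = 1$ (logged) rather than erroring.

**Metrics.** Accuracy is overall accuracy $(TP+TN)/N$; precision
$TP/(TP+FP)$ and recall $TP/(TP+FN)$ with a declared positive class.
Zero-denominator cases are reported as `NA` — never silently 0 or 1 — and
excluded from censuses with a logged count; scoring them would bias the
census counts. A balanced-accuracy field is included because some accuracy
definitions in this literature average per-class rates.

**Splitting.** Train size is $\mathrm{round}(f \cdot n)$, apportioned across
classes by largest remainder and clamped so both classes appear on both
sides. Stratification is the default: an unstratified 30-sample split can
easily produce a single-class test set, making accuracy ill-defined; plain
random splits remain available (`stratified = FALSE`).

## The synthetic world

`generate_dataset` emulates the structure of two-class microarray studies,
not their biology: Gaussian noise of SD `noise_sd` (log-intensity-like
continuous values), `n_informative` features with a between-class mean shift
of `effect_size` noise-SDs, and optional redundant blocks whose members
share a per-sample latent factor,
$x = \sqrt{\rho}\, z + \sqrt{1-\rho}\, \varepsilon$, giving within-block
correlation $\approx \rho$. Redundant blocks plant solution multiplicity by
construction: three blocks of three exchangeable strong markers guarantee
feature-disjoint triplets with equal predictive content.

Presets freeze the two regimes the screens are designed around:

| preset | features | samples | informative | effect | blocks | rationale |
|---|---|---|---|---|---|---|
| `easy` | 1000 | 30+30 | 12 | 2.5 | 3 × 3, ρ = 0.8 | near-ceiling accuracy, multiplicity by construction |
| `difficult` | 2000 | 15+15 | 10 | 0.8 | none | weak signal, small n |

Effect 2.5 puts single-feature Bayes accuracy near 0.89 and 3-feature
accuracy near ceiling (the "easy" regime where a 0.9 cutoff census is
populated); effect 0.8 with 30 samples keeps accuracies well below ceiling
(the "difficult" regime). Sample sizes, feature counts and the minority of
informative features mirror the typical published two-class microarray
study. These values were fixed before the acceptance checks were run and
are not tuned.

What a green test does **not** establish: the generator has no heavy tails,
no count noise, no batch or array effects, no correlation between
informative and background features, and mean-shift-only signal — real
expression data are harsher on every axis. Green acceptance shows the
machinery reproduces the multiplicity phenomenon in a world where it
provably exists, not that any particular real dataset exhibits it.

## Numerical and degenerate-case decisions

- Pseudoinverse tolerance $10^{-10}$ (relative) on singular values.
- RNG: Mersenne-Twister with inversion normals, pinned inside the package so
  results are stable across sessions; all seeded draws save and restore the
  caller's RNG state.
- Seeds: run $i$ of a screen uses `base_seed + i`; per-triplet splits use
  `split seed + index`. Manifests record every seed, and a rerun from a
  manifest is byte-identical on all numeric TSVs.
- Missing values are load-time errors (no imputation); non-numeric cells and
  duplicate ids fail naming the offending row/column.
- When the positive class is not declared it defaults to the minority class
  (tie → lexicographically smaller label), logged.
- Degenerate inputs: empty prediction sets return empty vectors; single-class
  training data errors; `best10` on fewer than 10 defined records returns
  all of them, flagged.

## Known limitations

- The triplet screen is exhaustive by design and scales as $O(k^3)$ fits;
  $k = 50$ (19,600 ELM fits) runs in about a minute of one CPU, but much
  larger $k$ calls for a different search strategy, which is out of scope.
- Only binary classification; multi-class, kernel and sequential ELM
  variants are out of scope.
- Precision/recall censuses depend on the declared positive class; swapping
  it swaps the meaning of both.
- The plots are presentation artifacts; every plotted number is also in a
  TSV, and the TSVs are the record.
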