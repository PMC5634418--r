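# multisol

Solution multiplicity ("Rashomon") screens for two-group expression-based
classification.

## The problem

In biomarker discovery it is tempting to treat *the* trained classifier or
*the* selected gene panel as the answer. On typical two-class expression
datasets — thousands of probes, tens of samples — that answer is rarely
unique: many independently trained models, and many distinct small feature
subsets, reach near-identical held-out performance. `multisol` provides the
machinery to demonstrate and quantify this multiplicity:

- an **extreme learning machine (ELM)** binary classifier built from
  scratch: a single hidden layer with seeded random, frozen input weights
  `W ∈ R^{n×m}` and biases `b`, hidden activations `H = tanh(WX + b)`, and a
  readout `β` fitted by minimum-norm least squares
  (`β = H⁺ y`, labels encoded 0/1, decision cut at 0.5). Each trained model
  is represented by its extractable weight matrix `W`;
- per-feature **two-sample t-test ranking** (Welch by default);
- a **repeated-fit model screen**: many seeded ELM fits on a fixed feature
  set (the t-test top 20, or all features), a *census* of runs whose test
  accuracy exceeds a cutoff (strictly), and comparison of tied-best models
  via the elementwise difference matrix `|W₁ − W₂|` — a nonzero maximum
  entry shows two equally accurate models are genuinely different solutions;
- an **exhaustive triplet screen**: every `C(k,3)` subset of the top-`k`
  (default 50, so 19,600) ranked features fitted as a 3-feature ELM on a
  shared stratified 80/20 split and censused by accuracy, precision
  (`TP/(TP+FP)`) and recall (`TP/(TP+FN)`), with rank-dispersion statistics
  of the best 10 per metric;
- a seeded **synthetic two-group generator** (Gaussian noise, planted mean
  shifts, redundant correlated feature blocks) so the whole pipeline — and
  the multiplicity phenomenon itself — is testable without external data.

## Worked example

```r
library(multisol)

ds <- generate_dataset(synthetic_preset("easy", seed = 1))
ds
#> ExpressionDataset: 1000 features x 60 samples
#>   classes: 'case' (n=30), 'control' (n=30) | positive: 'case'

rf <- rank_features(ds)
head(rf, 3)
#>   feature_id        t            p rank
#> 1      f0010 10.96030 2.335530e-15    1
#> 2      f0012 10.03951 5.518976e-14    2
#> 3      f0004  9.22734 5.668327e-13    3

screen <- run_screen(ds, screen_config(n_runs = 500, cutoff = 0.9,
  split_spec = split_spec(0.7, seed = 1), base_seed = 1))
screen
#> ScreenReport (ELM, Top20Features): 500 runs, cutoff 0.900 (strict)
#>   498 above cutoff; min/max above: 0.944 / 1.000; best 1.000 (435 tied)

pair <- best_pair(screen, tiebreak_seed = 1)
weight_difference(pair[[1]], pair[[2]])
#> DifferenceMatrix: 150 x 20, max difference 1.976

trip <- screen_triplets(ds, rf, k = 50, cutoffs = c(accuracy = 0.9),
  elm_config = elm_config(n_hidden = 150, seed = 1),
  split_spec = split_spec(0.8, seed = 1))
trip
#> TripletScreenReport: 19600 triplets of top-50 features (shared split: TRUE)
#>   accuracy >= 0.900: 994 triplets
```

Reading: 498 of 500 independently seeded ELMs clear the 0.9 accuracy cutoff
and 435 tie at the best accuracy 1.000, yet two of the tied-best models
differ in some hidden weight by 1.976 — equally good, structurally distinct
solutions. Likewise 994 different gene triplets reach ≥ 0.9 test accuracy;
the ten best tie at 1.0 with mean t-test ranks spread over (2.667, 4.333),
and the top triplet's members alone reach only e.g. 0.667 accuracy
(`single_feature_accuracy`) — the triplet works through complementarity,
not through one dominant marker.

`full_pipeline()` (or the `exec/multisol` CLI: `simulate`, `rank`, `screen`,
`triplets`, `report` subcommands) runs load → rank → model screen → best-pair
difference heatmap → triplet screen end to end, writing every number as TSV
plus a JSON manifest that reproduces the run byte-identically.

## Documentation

See `vignettes/solution-multiplicity.Rmd` for the model, the generator's
assumptions, parameter choices, and known limitations.
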